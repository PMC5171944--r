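#' Analysis configuration
#'
#' Collects the tunable parameters of the convergence analysis. Gates
#' (Shapiro-Wilk normality, Breusch-Pagan homoskedasticity) default to
#' alpha = 0.05; weights default to inverse uncertainty (1/s, not 1/s^2).
#'
#' @param alpha_gate gate significance level for the normality and
#'   homoskedasticity checks
#' @param weight_power 1 for 1/s weights, 2 for 1/s^2
#' @param include_rh_cwd include Rh-cwd in biometric NEP and Reco
#' @param uncertainty list from [uncertainty_config()]
#' @param gapfill list from [gapfill_config()]
#' @return named list
#' @export
analysis_config <- function(alpha_gate = 0.05, weight_power = 1,
                            include_rh_cwd = TRUE,
                            uncertainty = uncertainty_config(),
                            gapfill = gapfill_config()) {
  list(alpha_gate = alpha_gate, weight_power = weight_power,
       include_rh_cwd = include_rh_cwd, uncertainty = uncertainty,
       gapfill = gapfill)
}

# Which screen variables apply to which flux (NA pattern of the
# variant-by-flux screen table). Site/environmental covariates apply to
# all three fluxes.
screen_plan <- function() {
  cov_all <- c("elevation_variability", "topographical_slope", "lai",
               "leaf_type", "leaf_habit", "fertility", "climate_zone",
               "mean_annual_precipitation", "mean_annual_temperature")
  list(
    NEP = c(cov_all, "fine_root_npp_method", "allometry_quality",
            "leaf_npp_method", "rh_soil_method", "rh_cwd_considered"),
    Reco = c(cov_all, "soil_chamber", "co2_scrubbing", "rh_cwd_considered",
             "rsoil_model_drivers", "rleaf_model_drivers",
             "rleaf_parameterization", "rleaf_variable_q10",
             "light_inhibition_considered", "leaf_growth_respiration",
             "wood_growth_respiration", "rwood_model_drivers",
             "rwood_scaling", "branch_stem_separated"),
    GPP = c(cov_all, "fine_root_npp_method", "allometry_quality",
            "leaf_npp_method", "rleaf_model_drivers",
            "rleaf_parameterization", "rleaf_variable_q10",
            "light_inhibition_considered", "leaf_growth_respiration",
            "wood_growth_respiration", "rwood_model_drivers",
            "rwood_scaling", "branch_stem_separated")
  )
}

pair_uncertainty <- function(sites, flux) {
  low <- tolower(flux)
  sqrt(sites[[paste0("s_", low, "_ec")]]^2 +
         sites[[paste0("s_", low, "_bm")]]^2)
}

paired_summary_row <- function(flux, stratum, bm, ec, alpha_gate) {
  keep <- stats::complete.cases(bm, ec)
  bm <- bm[keep]; ec <- ec[keep]
  n <- length(bm)
  if (n < 3) {
    return(tibble(flux_kind = flux, stratum = stratum, n = n,
                  abs_diff_mean = NA_real_, abs_diff_sem = NA_real_,
                  rel_diff_mean = NA_real_, rel_diff_sem = NA_real_,
                  p_value = NA_real_, test_used = NA_character_,
                  mark = ""))
  }
  pc <- paired_compare(bm, ec, alpha_gate)
  if (flux == "NEP") {
    rdm <- NA_real_; rds <- NA_real_
  } else {
    rd <- relative_difference(bm, ec, flux)
    rdm <- 100 * mean(rd)
    rds <- 100 * stats::sd(rd) / sqrt(n)
  }
  tibble(flux_kind = flux, stratum = stratum, n = n,
         abs_diff_mean = pc$mean_difference, abs_diff_sem = pc$sem,
         rel_diff_mean = rdm, rel_diff_sem = rds,
         p_value = pc$p_value, test_used = pc$test_used,
         mark = signif_marks(pc$p_value))
}

#' Run the full EC-BM convergence analysis
#'
#' Executes the analysis sequence on a site table: (1) major-axis
#' regressions of BM on EC for NEP, Reco and GPP; (2) normality-gated
#' paired comparisons per flux, globally and per climate zone, with
#' absolute differences (BM - EC) for all fluxes and relative differences
#' for Reco and GPP; (3) inverse-uncertainty-weighted univariate screens
#' of the between-method difference against every applicable site
#' covariate and methodological variant, with leave-one-out outlier
#' sensitivity for numeric covariates; (4) a two-way type-II ANOVA of the
#' Reco relative difference on light-inhibition accounting x Rleaf
#' parameterization within the NSF-chamber subset; (5) the cross-site
#' budget composition summary; (6) the comparison of EC NEP with
#' stock-inventory NEP where repeated inventories exist; and (7) the NPP
#' gap-filling sensitivity report. Sites are never dropped as outliers;
#' strata with fewer than 3 pairs are reported as NA.
#'
#' @param sites site table from [read_site_table()] or
#'   [generate_dataset()]
#' @param config list from [analysis_config()]
#' @return list of class `convergence_report`: budgets, fig2 (MA
#'   regressions), table2 (paired comparisons), table3 (screens),
#'   outliers, anova_nsf, composition, nep_stock, gapfill, log
#' @export
run_convergence_analysis <- function(sites, config = analysis_config()) {
  if (!is.data.frame(sites) || nrow(sites) == 0) {
    stop("run_convergence_analysis(): empty site table")
  }
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  budgets <- dplyr::bind_cols(
    tibble(site_id = sites$site_id),
    assemble_bm_budget(sites, include_rh_cwd = config$include_rh_cwd))
  for (fx in c("nep", "reco", "gpp")) {
    bad <- is.na(budgets[[paste0(fx, "_bm")]])
    for (i in which(bad)) {
      note("site %s: %s_bm not computable (%s)", budgets$site_id[i], fx,
           budgets$completeness_flags[i])
    }
  }
  sites <- assign_uncertainties(sites, config$uncertainty)
  dat <- dplyr::left_join(sites, budgets, by = "site_id")

  flux_cols <- list(NEP = c("nep_bm", "nep_ec"),
                    Reco = c("reco_bm", "reco_ec"),
                    GPP = c("gpp_bm", "gpp_ec"))

  # (1) MA regressions, BM (y) on EC (x)
  fig2 <- purrr::map(flux_cols, function(cc) {
    keep <- stats::complete.cases(dat[[cc[1]]], dat[[cc[2]]])
    if (sum(keep) < 3) return(NULL)
    ma_regression(dat[[cc[2]]][keep], dat[[cc[1]]][keep])
  })

  # (2) paired comparisons per stratum
  strata <- c("global", "boreal", "temperate", "tropical")
  table2 <- purrr::map_dfr(names(flux_cols), function(fx) {
    cc <- flux_cols[[fx]]
    purrr::map_dfr(strata, function(st) {
      idx <- if (st == "global") rep(TRUE, nrow(dat))
             else dat$climate_zone == st
      paired_summary_row(fx, st, dat[[cc[1]]][idx], dat[[cc[2]]][idx],
                         config$alpha_gate)
    })
  })

  # (3) weighted screens of the difference against covariates/variants
  plan <- screen_plan()
  table3 <- purrr::map_dfr(names(plan), function(fx) {
    cc <- flux_cols[[fx]]
    bm <- dat[[cc[1]]]; ec <- dat[[cc[2]]]
    resp <- if (fx == "NEP") bm - ec else {
      suppressWarnings(relative_difference(bm, ec, fx))
    }
    w <- inverse_uncertainty_weights(pair_uncertainty(dat, fx),
                                     config$weight_power)
    purrr::map_dfr(plan[[fx]], function(v) {
      if (!v %in% names(dat)) {
        note("screen %s ~ %s skipped: column absent", fx, v)
        return(NULL)
      }
      x <- dat[[v]]
      sub <- rep(TRUE, nrow(dat))
      if (v == "co2_scrubbing") sub <- !is.na(dat$soil_chamber) &
          dat$soil_chamber == "NSF"
      if (v == "leaf_npp_method" && "leaf_habit" %in% names(dat)) {
        sub <- !is.na(dat$leaf_habit) & dat$leaf_habit == "evergreen"
      }
      if (v == "soil_chamber") {
        x <- ifelse(x == "other", NA_character_, x)  # too rare to test
      }
      if (is.logical(x)) x <- ifelse(x, "yes", "no")
      fit <- tryCatch(
        weighted_screen(resp[sub], x[sub], w[sub], config$alpha_gate),
        error = function(e) {
          note("screen %s ~ %s failed: %s", fx, v, conditionMessage(e))
          NULL
        })
      if (is.null(fit)) return(NULL)
      tibble(flux_kind = fx, variable = v, n = fit$n,
             p_value = fit$p_value, r_squared = fit$r_squared,
             heteroskedastic = fit$heteroskedastic,
             inference_method = fit$inference_method,
             mark = signif_marks(fit$p_value))
    })
  })

  # leave-one-out sensitivity for the numeric covariates
  numeric_covs <- c("elevation_variability", "topographical_slope", "lai",
                    "mean_annual_precipitation", "mean_annual_temperature")
  outliers <- purrr::map_dfr(names(flux_cols), function(fx) {
    cc <- flux_cols[[fx]]
    bm <- dat[[cc[1]]]; ec <- dat[[cc[2]]]
    resp <- if (fx == "NEP") bm - ec else {
      suppressWarnings(relative_difference(bm, ec, fx))
    }
    w <- inverse_uncertainty_weights(pair_uncertainty(dat, fx),
                                     config$weight_power)
    purrr::map_dfr(intersect(numeric_covs, names(dat)), function(v) {
      keep <- stats::complete.cases(resp, dat[[v]], w)
      if (sum(keep) < 5) return(NULL)
      sens <- tryCatch(
        outlier_sensitivity(resp[keep], dat[[v]][keep], w[keep],
                            config$alpha_gate),
        error = function(e) NULL)
      if (is.null(sens)) return(NULL)
      flagged <- sens[sens$crosses_05 | sens$crosses_10, , drop = FALSE]
      tibble(flux_kind = fx, variable = v,
             p_full = attr(sens, "p_full"),
             n_influential = nrow(flagged),
             p_range_loo = paste0(signif(min(sens$p_loo), 3), "-",
                                  signif(max(sens$p_loo), 3)))
    })
  })

  # (4) NSF subset: light inhibition x Rleaf parameterization
  anova_nsf <- NULL
  if (all(c("soil_chamber", "light_inhibition_considered",
            "rleaf_parameterization") %in% names(dat))) {
    nsf <- !is.na(dat$soil_chamber) & dat$soil_chamber == "NSF"
    rd <- suppressWarnings(
      relative_difference(dat$reco_bm, dat$reco_ec, "Reco"))
    keep <- nsf & stats::complete.cases(
      rd, dat$light_inhibition_considered, dat$rleaf_parameterization)
    if (sum(keep) >= 6) {
      anova_nsf <- tryCatch(
        two_way_anova(rd[keep],
                      ifelse(dat$light_inhibition_considered[keep],
                             "yes", "no"),
                      dat$rleaf_parameterization[keep]),
        error = function(e) {
          note("NSF two-way ANOVA failed: %s", conditionMessage(e))
          NULL
        })
    } else {
      note("NSF two-way ANOVA skipped: only %d usable NSF sites",
           sum(keep))
    }
  }

  # (5) composition of the biometric budget
  composition <- tryCatch(composition_summary(sites),
                          error = function(e) {
                            note("composition summary failed: %s",
                                 conditionMessage(e))
                            NULL
                          })

  # (6) stock-inventory NEP vs EC NEP
  nep_stock <- NULL
  stock_cols <- c("time_start", "time_end", "wood_stock_start",
                  "wood_stock_end", "soil_stock_start", "soil_stock_end")
  if (all(stock_cols %in% names(dat))) {
    has <- stats::complete.cases(dat[, stock_cols])
    if (sum(has) >= 3) {
      nep_ds <- nep_from_stocks(dat[has, ])
      nep_stock <- paired_summary_row("NEP", "stock_inventory",
                                      nep_ds, dat$nep_ec[has],
                                      config$alpha_gate)
    } else {
      note("stock-inventory comparison skipped: %d sites with inventories",
           sum(has))
    }
  }

  # (7) NPP gap-filling sensitivity
  gapfill <- NULL
  gf_in <- dplyr::left_join(
    budgets[, c("site_id", "npp_total")],
    sites[, intersect(c("site_id", "npp_wood_aboveground",
                        "npp_branch_turnover",
                        "npp_branch_turnover_measured",
                        "npp_mycorrhiza_measured"), names(sites))],
    by = "site_id")
  gapfill <- gapfill_sites(gf_in, config$gapfill)
  note("gap-filled NPP mean increase: %.1f%%",
       100 * mean(gapfill$increase_fraction, na.rm = TRUE))

  structure(list(
    budgets = budgets, fig2 = fig2, table2 = table2, table3 = table3,
    outliers = outliers, anova_nsf = anova_nsf, composition = composition,
    nep_stock = nep_stock, gapfill = gapfill, log = log_lines),
    class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("EC-BM convergence report\n")
  cat("  major-axis regressions (BM vs EC):\n")
  for (fx in names(x$fig2)) {
    f <- x$fig2[[fx]]
    if (is.null(f)) next
    cat(sprintf("    %-4s slope %.2f (CI95 %.2f-%.2f), R2 %.2f, n %d\n",
                fx, f$slope, f$slope_ci95[1], f$slope_ci95[2],
                f$r_squared, f$n))
  }
  glob <- x$table2[x$table2$stratum == "global", ]
  cat("  global paired comparisons (BM - EC):\n")
  for (i in seq_len(nrow(glob))) {
    cat(sprintf("    %-4s n %2d  diff %6.0f +/- %.0f  P %.3g%s\n",
                glob$flux_kind[i], glob$n[i], glob$abs_diff_mean[i],
                glob$abs_diff_sem[i], glob$p_value[i], glob$mark[i]))
  }
  invisible(x)
}

#' Compare daytime- and nighttime-partitioned EC fluxes
#'
#' For sites carrying both EC partitioning variants (columns
#' `reco_ec_daytime` / `gpp_ec_daytime` alongside the nighttime-derived
#' `reco_ec` / `gpp_ec`), runs the normality-gated paired comparison and
#' the relative-difference summary between the two variants.
#'
#' @param sites site table
#' @param alpha_gate gate level for the paired test
#' @return tibble with one row per flux: n, rel_diff_mean (%),
#'   rel_diff_sem, p_value, test_used; NA row when no dual-variant sites
#' @export
compare_partitioning_variants <- function(sites, alpha_gate = 0.05) {
  purrr::map_dfr(c("Reco", "GPP"), function(fx) {
    low <- tolower(fx)
    day_col <- paste0(low, "_ec_daytime")
    night_col <- paste0(low, "_ec")
    if (!day_col %in% names(sites)) {
      return(tibble(flux_kind = fx, n = 0L, rel_diff_mean = NA_real_,
                    rel_diff_sem = NA_real_, p_value = NA_real_,
                    test_used = NA_character_))
    }
    day <- sites[[day_col]]; night <- sites[[night_col]]
    keep <- stats::complete.cases(day, night)
    n <- sum(keep)
    if (n < 3) {
      return(tibble(flux_kind = fx, n = n, rel_diff_mean = NA_real_,
                    rel_diff_sem = NA_real_, p_value = NA_real_,
                    test_used = NA_character_))
    }
    rd <- relative_difference(day[keep], night[keep], fx)
    if (stats::sd(day[keep] - night[keep]) == 0) {
      return(tibble(flux_kind = fx, n = n, rel_diff_mean = 0,
                    rel_diff_sem = 0, p_value = 1,
                    test_used = "degenerate"))
    }
    pc <- paired_compare(day[keep], night[keep], alpha_gate)
    tibble(flux_kind = fx, n = n,
           rel_diff_mean = 100 * mean(rd),
           rel_diff_sem = 100 * stats::sd(rd) / sqrt(n),
           p_value = pc$p_value, test_used = pc$test_used)
  })
}

#' Write the report tables of a convergence analysis
#'
#' @param report a `convergence_report`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$table2, file.path(dir, "table2.csv"), na = "")
  readr::write_csv(report$table3, file.path(dir, "table3.csv"), na = "")
  readr::write_csv(report$budgets, file.path(dir, "budgets.csv"), na = "")
  if (!is.null(report$composition)) {
    readr::write_csv(report$composition,
                     file.path(dir, "composition.csv"), na = "")
  }
  if (!is.null(report$gapfill)) {
    readr::write_csv(report$gapfill, file.path(dir, "gapfill.csv"),
                     na = "")
  }
  fig2 <- purrr::imap(report$fig2, function(f, fx) {
    if (is.null(f)) return(NULL)
    list(flux = fx, slope = f$slope, intercept = f$intercept,
         ci95 = f$slope_ci95, r_squared = f$r_squared,
         p_value = f$p_value, n = f$n)
  })
  jsonlite::write_json(fig2, file.path(dir, "fig2_stats.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(report$log, file.path(dir, "log.txt"))
  invisible(dir)
}
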