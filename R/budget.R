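#' Complete the soil-respiration partition
#'
#' Soil CO2 efflux splits into root (autotrophic) and heterotrophic parts,
#' Rsoil = Rroot + Rh-soil. Given any two members the third is implied;
#' given all three their consistency is asserted.
#'
#' @param rsoil,rroot,rh_soil fluxes in gC m-2 y-1; exactly one may be `NA`
#' @param tol consistency tolerance when all three are present, gC m-2 y-1
#' @return named list with all of `rsoil`, `rroot`, `rh_soil` filled
#' @examples
#' partition_rsoil(650, 300, NA) # rh_soil = 350
#' @export
partition_rsoil <- function(rsoil = NA, rroot = NA, rh_soil = NA, tol = 1) {
  present <- !is.na(c(rsoil, rroot, rh_soil))
  if (sum(present) < 2) {
    stop("partition_rsoil(): at least two of rsoil, rroot, rh_soil required")
  }
  if (all(present)) {
    if (abs(rsoil - (rroot + rh_soil)) > tol) {
      stop(sprintf(
        "inconsistent soil-respiration partition: %.1f != %.1f + %.1f",
        rsoil, rroot, rh_soil))
    }
  } else if (is.na(rsoil)) {
    rsoil <- rroot + rh_soil
  } else if (is.na(rroot)) {
    rroot <- rsoil - rh_soil
  } else {
    rh_soil <- rsoil - rroot
  }
  if (rroot < -tol || rh_soil < -tol || rsoil < 0) {
    stop("inconsistent soil-respiration partition: negative component")
  }
  list(rsoil = rsoil, rroot = max(rroot, 0), rh_soil = max(rh_soil, 0))
}

npp_part_fields <- function() {
  c("npp_wood_aboveground", "npp_foliage", "npp_fineroot", "npp_coarseroot",
    "npp_understory", "npp_branch_turnover", "npp_reproductive", "npp_other")
}

#' Assemble a biometric carbon budget from component fluxes
#'
#' Combines biometric component fluxes into the three ecosystem-level
#' fluxes using the budget identities
#' NEP = NPP - Rh, Reco = Ra + Rh, GPP = NPP + Ra, so that
#' GPP - Reco = NEP holds exactly by construction. Total NPP is the sum of
#' all reported NPP parts (wood, foliage and fine-root parts are required;
#' understory, branch turnover, reproductive and other parts are added when
#' present). Aboveground autotrophic respiration is Rleaf + Rwood, plus
#' understory respiration when reported separately. The soil-respiration
#' partition is completed via [partition_rsoil()] when only two members are
#' given. Rh-cwd is treated as 0 when absent or excluded and this is noted
#' in the completeness flags.
#'
#' Per-flux preconditions follow data availability: Reco needs Rleaf, Rwood
#' and Rsoil; NEP additionally needs the heterotrophic part of Rsoil; GPP
#' needs the root (autotrophic) part. A flux whose preconditions fail is
#' returned as `NA` with a flag, leaving the others intact.
#'
#' @param components one-row data frame, list, or multi-row data frame of
#'   biometric component fluxes (columns among [bm_component_fields()])
#' @param include_rh_cwd include Rh-cwd in NEP and Reco when present
#' @return tibble with one row per input row: npp_total, ra_aboveground,
#'   nep_bm, reco_bm, gpp_bm, completeness_flags (semicolon-joined tokens)
#' @export
assemble_bm_budget <- function(components, include_rh_cwd = TRUE) {
  comp <- if (is.data.frame(components)) as_tibble(components)
          else as_tibble(as.list(components))
  for (nm in bm_component_fields()) {
    if (!nm %in% names(comp)) comp[[nm]] <- NA_real_
  }
  n <- nrow(comp)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    row <- comp[i, ]
    flags <- character()
    g <- function(nm) as.numeric(row[[nm]])

    core <- c("npp_wood_aboveground", "npp_foliage", "npp_fineroot")
    npp_parts <- vapply(npp_part_fields(), g, numeric(1))
    npp_ok <- all(!is.na(npp_parts[core]))
    npp_total <- if (npp_ok) sum(npp_parts, na.rm = TRUE) else NA_real_
    if (npp_ok) {
      omitted <- names(npp_parts)[is.na(npp_parts)]
      flags <- c(flags, paste0(omitted, "_omitted"))
    } else {
      flags <- c(flags, "npp_core_incomplete")
    }

    ra_ok <- !is.na(g("ra_leaf")) && !is.na(g("ra_wood"))
    ra_above <- if (ra_ok) {
      sum(c(g("ra_leaf"), g("ra_wood"), g("ra_understory")), na.rm = TRUE)
    } else NA_real_
    if (ra_ok && is.na(g("ra_understory"))) {
      flags <- c(flags, "ra_understory_omitted")
    }
    if (!ra_ok) flags <- c(flags, "ra_aboveground_incomplete")

    part <- tryCatch(
      partition_rsoil(g("rsoil"), g("rroot"), g("rh_soil")),
      error = function(e) NULL)
    if (is.null(part)) {
      # keep whatever single members exist for partial budgets
      part <- list(rsoil = g("rsoil"), rroot = g("rroot"),
                   rh_soil = g("rh_soil"))
      flags <- c(flags, "rsoil_partition_unavailable")
    }

    rh_cwd <- g("rh_cwd")
    use_cwd <- include_rh_cwd && !is.na(rh_cwd)
    if (!use_cwd) {
      flags <- c(flags, if (is.na(rh_cwd)) "rh_cwd_omitted"
                 else "rh_cwd_excluded")
    }
    cwd <- if (use_cwd) rh_cwd else 0

    nep <- if (npp_ok && !is.na(part$rh_soil)) {
      npp_total - part$rh_soil - cwd
    } else NA_real_
    reco <- if (ra_ok && !is.na(part$rsoil)) {
      ra_above + part$rsoil + cwd
    } else NA_real_
    gpp <- if (npp_ok && ra_ok && !is.na(part$rroot)) {
      npp_total + ra_above + part$rroot
    } else NA_real_

    # enforce exact closure when all three are computable: GPP - Reco = NEP
    # holds algebraically because Rsoil = Rroot + Rh-soil, but floating
    # point summation order can leave an ulp; re-derive NEP from the pair.
    if (!is.na(nep) && !is.na(reco) && !is.na(gpp)) nep <- gpp - reco

    out[[i]] <- tibble(
      npp_total = npp_total, ra_aboveground = ra_above,
      nep_bm = nep, reco_bm = reco, gpp_bm = gpp,
      completeness_flags = paste(flags, collapse = ";"))
  }
  dplyr::bind_rows(out)
}

#' Net ecosystem production from repeated stock inventories
#'
#' An independent biometric route to NEP that avoids NPP and Rh entirely:
#' the change in the two major ecosystem carbon stocks (wood and soil)
#' between two inventories, divided by the interval, plus lateral carbon
#' losses (harvest exports, DOC leaching) which left the system without
#' being respired.
#'
#' @param inv data frame (or one-row list) with time_start, time_end,
#'   wood_stock_start, wood_stock_end, soil_stock_start, soil_stock_end,
#'   lateral_losses (gC m-2 y-1; 0 when absent)
#' @return numeric vector of NEP (gC m-2 y-1), positive = carbon sink
#' @examples
#' nep_from_stocks(data.frame(time_start = 2000, time_end = 2002,
#'   wood_stock_start = 10000, wood_stock_end = 10300,
#'   soil_stock_start = 5000, soil_stock_end = 5050, lateral_losses = 25))
#' @export
nep_from_stocks <- function(inv) {
  inv <- as.data.frame(inv)
  dt <- inv$time_end - inv$time_start
  if (any(!is.na(dt) & dt <= 0)) {
    stop("nep_from_stocks(): time_end must exceed time_start")
  }
  losses <- if ("lateral_losses" %in% names(inv)) {
    ifelse(is.na(inv$lateral_losses), 0, inv$lateral_losses)
  } else 0
  delta <- (inv$wood_stock_end + inv$soil_stock_end) -
    (inv$wood_stock_start + inv$soil_stock_start)
  delta / dt + losses
}

#' Symmetric relative difference between method estimates
#'
#' (BM - EC) / ((BM + EC) / 2), the standard symmetric percentage-scale
#' discrepancy for strictly positive fluxes (Reco, GPP). For NEP, which
#' takes both signs, the statistic is undefined and refused.
#'
#' @param bm,ec flux estimates (gC m-2 y-1)
#' @param flux_kind one of "Reco", "GPP" ("NEP" errors)
#' @return dimensionless relative difference in (-2, 2)
#' @export
relative_difference <- function(bm, ec, flux_kind = "Reco") {
  if (flux_kind == "NEP") {
    stop("relative difference is unsupported for NEP: ",
         "the statistic is undefined for sign-changing fluxes")
  }
  flux_kind <- match.arg(flux_kind, c("Reco", "GPP"))
  mid <- (bm + ec) / 2
  if (any(!is.na(mid) & mid == 0)) {
    stop("relative difference undefined: bm + ec = 0")
  }
  (bm - ec) / mid
}

share_row <- function(parts) {
  tot <- sum(parts, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) return(rep(NA_real_, length(parts)))
  ifelse(is.na(parts), 0, parts) / tot
}

#' Cross-site composition of the biometric carbon budget
#'
#' Per-site component shares, averaged across sites (mean and s.e.m.,
#' s.e.m. = sd/sqrt(n)): NPP allocation (foliage / aboveground wood / roots
#' / other), aboveground+root autotrophic respiration partition (leaf /
#' wood / root), Reco partition (Rsoil / Rleaf / Rwood / Rh-cwd), the
#' autotrophic:heterotrophic split of Reco, and the fine-root share of
#' root NPP. Shares are computed over the components present at each site,
#' so each partition sums to 1 per site.
#'
#' @param components data frame of biometric components, one site per row
#' @return tibble with columns partition, component, mean_share, sem_share,
#'   n_sites
#' @export
composition_summary <- function(components) {
  comp <- as_tibble(components)
  if (nrow(comp) < 2) {
    stop("composition_summary() needs at least two sites")
  }
  for (nm in bm_component_fields()) {
    if (!nm %in% names(comp)) comp[[nm]] <- NA_real_
  }
  g <- function(nm) comp[[nm]]
  rows <- list()
  push <- function(partition, shares_mat) {
    for (j in colnames(shares_mat)) {
      v <- shares_mat[, j]
      v <- v[!is.na(v)]
      n <- length(v)
      if (n == 0) next
      rows[[length(rows) + 1]] <<- tibble(
        partition = partition, component = j,
        mean_share = mean(v),
        sem_share = if (n > 1) stats::sd(v) / sqrt(n) else 0,
        n_sites = n)
    }
  }

  # NPP allocation
  npp_fol <- g("npp_foliage")
  npp_wood <- g("npp_wood_aboveground")
  npp_root <- g("npp_fineroot") +
    ifelse(is.na(g("npp_coarseroot")), 0, g("npp_coarseroot"))
  npp_other <- rowSums(cbind(g("npp_understory"), g("npp_branch_turnover"),
                             g("npp_reproductive"), g("npp_other")),
                       na.rm = TRUE)
  npp_mat <- t(apply(cbind(foliage = npp_fol, wood = npp_wood,
                           root = npp_root, other = npp_other), 1,
                     share_row))
  colnames(npp_mat) <- c("foliage", "wood", "root", "other")
  push("npp", npp_mat)

  # fine-root share of root NPP
  fr <- g("npp_fineroot") / npp_root
  rows[[length(rows) + 1]] <- {
    v <- fr[!is.na(fr)]
    tibble(partition = "root_npp", component = "fine_root",
           mean_share = mean(v),
           sem_share = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                       else 0,
           n_sites = length(v))
  }

  # autotrophic respiration partition (leaf / wood / root)
  ra_mat <- t(apply(cbind(leaf = g("ra_leaf"), wood = g("ra_wood"),
                          root = g("rroot")), 1, share_row))
  colnames(ra_mat) <- c("leaf", "wood", "root")
  push("ra", ra_mat)

  # Reco partition (Rsoil / Rleaf / Rwood / Rh-cwd)
  reco_mat <- t(apply(cbind(rsoil = g("rsoil"), rleaf = g("ra_leaf"),
                            rwood = g("ra_wood"), rh_cwd = g("rh_cwd")), 1,
                      share_row))
  colnames(reco_mat) <- c("rsoil", "rleaf", "rwood", "rh_cwd")
  push("reco", reco_mat)

  # autotrophic vs heterotrophic split of Reco
  ra_tot <- g("ra_leaf") + g("ra_wood") +
    ifelse(is.na(g("ra_understory")), 0, g("ra_understory")) + g("rroot")
  rh_tot <- g("rh_soil") + ifelse(is.na(g("rh_cwd")), 0, g("rh_cwd"))
  arh_mat <- t(apply(cbind(ra = ra_tot, rh = rh_tot), 1, share_row))
  colnames(arh_mat) <- c("ra", "rh")
  push("ra_rh", arh_mat)

  dplyr::bind_rows(rows)
}
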