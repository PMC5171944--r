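#' @importFrom tibble tibble as_tibble
NULL

# Canonical site-table schema. One site per row, fluxes in gC m-2 y-1.
# `class`: num / int / chr / lgl / enum; enum levels validated
# case-insensitively on read.
site_schema <- function() {
  enum <- function(...) list(class = "enum", levels = c(...))
  num <- list(class = "num"); int <- list(class = "int")
  chr <- list(class = "chr"); lgl <- list(class = "lgl")
  list(
    required = list(
      site_id = chr,
      latitude = num,
      longitude = num,
      climate_zone = enum("boreal", "temperate", "tropical"),
      years_measured = int,
      data_quality = enum("high", "fair"),
      nep_ec = num, reco_ec = num, gpp_ec = num,
      ec_partitioning = enum("nighttime", "daytime", "sundown")
    ),
    optional = list(
      # biometric component fluxes
      npp_wood_aboveground = num, npp_foliage = num, npp_fineroot = num,
      npp_coarseroot = num, npp_understory = num, npp_branch_turnover = num,
      npp_reproductive = num, npp_other = num,
      ra_leaf = num, ra_wood = num, ra_understory = num,
      rsoil = num, rroot = num, rh_soil = num, rh_cwd = num,
      # methodological variants of the BM technique
      fine_root_npp_method = enum("sequential_coring", "ingrowth_cores",
                                  "minirhizotron", "other"),
      allometry_quality = enum("low", "moderate", "high"),
      leaf_npp_method = enum("litter_trap", "allometry"),
      soil_chamber = enum("NSNF", "NSF", "other"),
      co2_scrubbing = lgl,
      rh_soil_method = enum("root_exclusion", "root_respiration",
                            "component_integration", "other"),
      rh_cwd_considered = lgl,
      rsoil_model_drivers = enum("temperature", "temperature_and_water"),
      rleaf_model_drivers = enum("temperature", "temperature_plus_other"),
      rleaf_parameterization = enum("site_specific", "generic"),
      rleaf_variable_q10 = lgl,
      light_inhibition_considered = lgl,
      leaf_growth_respiration = lgl,
      wood_growth_respiration = lgl,
      rwood_model_drivers = enum("temperature", "temperature_plus_other"),
      rwood_scaling = enum("wood_volume", "wood_area"),
      branch_stem_separated = lgl,
      npp_branch_turnover_measured = lgl,
      npp_mycorrhiza_measured = lgl,
      # environmental / stand covariates
      mean_annual_temperature = num, mean_annual_precipitation = num,
      fertility = enum("low", "medium", "high"),
      leaf_type = enum("needleleaved", "broadleaved", "mixed"),
      leaf_habit = enum("evergreen", "deciduous", "mixed"),
      lai = num, elevation_variability = num, topographical_slope = num,
      # repeated stock inventories
      time_start = num, time_end = num,
      wood_stock_start = num, wood_stock_end = num,
      soil_stock_start = num, soil_stock_end = num,
      lateral_losses = num,
      # optional extras used by some analyses
      years_measured_ec = int, years_measured_bm = int,
      reco_ec_daytime = num, gpp_ec_daytime = num
    )
  )
}

#' Names of the biometric component-flux columns
#' @return character vector of column names
#' @export
bm_component_fields <- function() {
  c("npp_wood_aboveground", "npp_foliage", "npp_fineroot", "npp_coarseroot",
    "npp_understory", "npp_branch_turnover", "npp_reproductive", "npp_other",
    "ra_leaf", "ra_wood", "ra_understory",
    "rsoil", "rroot", "rh_soil", "rh_cwd")
}

#' Names of the methodological-variant columns
#' @return character vector of column names
#' @export
method_profile_fields <- function() {
  c("fine_root_npp_method", "allometry_quality", "leaf_npp_method",
    "soil_chamber", "co2_scrubbing", "rh_soil_method", "rh_cwd_considered",
    "rsoil_model_drivers", "rleaf_model_drivers", "rleaf_parameterization",
    "rleaf_variable_q10", "light_inhibition_considered",
    "leaf_growth_respiration", "wood_growth_respiration",
    "rwood_model_drivers", "rwood_scaling", "branch_stem_separated",
    "ec_partitioning",
    "npp_branch_turnover_measured", "npp_mycorrhiza_measured")
}

parse_schema_column <- function(x, name, spec) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) %in% c("", "NA")] <- NA_character_
  x <- trimws(x)
  switch(spec$class,
    chr = x,
    num = , int = {
      bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
      if (any(bad)) {
        stop(sprintf("column '%s': unparseable numeric in row(s) %s",
                     name, paste(which(bad), collapse = ", ")))
      }
      out <- as.numeric(x)
      if (spec$class == "int") {
        if (any(!is.na(out) & out != round(out))) {
          stop(sprintf("column '%s': expected integer values", name))
        }
        out <- as.integer(round(out))
      }
      out
    },
    lgl = {
      lx <- tolower(x)
      map <- c("true" = TRUE, "t" = TRUE, "yes" = TRUE, "1" = TRUE,
               "false" = FALSE, "f" = FALSE, "no" = FALSE, "0" = FALSE)
      bad <- !is.na(lx) & !lx %in% names(map)
      if (any(bad)) {
        stop(sprintf("column '%s': unknown logical value in row(s) %s",
                     name, paste(which(bad), collapse = ", ")))
      }
      unname(map[lx])
    },
    enum = {
      idx <- match(tolower(x), tolower(spec$levels))
      bad <- !is.na(x) & is.na(idx)
      if (any(bad)) {
        stop(sprintf(
          "column '%s': unknown level(s) %s (expected one of: %s)",
          name, paste(unique(x[bad]), collapse = ", "),
          paste(spec$levels, collapse = ", ")))
      }
      spec$levels[idx]
    },
    stop("unknown schema class")
  )
}

#' Read a site table
#'
#' Reads a CSV with one forest site per row: EC fluxes (NEP/Reco/GPP and
#' the partitioning method used to derive Reco and GPP from NEP), biometric
#' component fluxes, methodological-variant labels, environmental
#' covariates and optional repeated stock inventories. Empty cells and the
#' string "NA" are read as missing; enum levels are matched
#' case-insensitively; unknown extra columns are preserved as-is.
#'
#' @param path CSV file path
#' @param schema_config optional named character vector remapping file
#'   column names to canonical ones, e.g. `c(nep_ec = "NEP_tower")` reads
#'   canonical `nep_ec` from file column `NEP_tower`.
#' @return tibble with canonical columns typed and validated
#' @seealso [validate_dataset()], [write_site_table()]
#' @export
read_site_table <- function(path, schema_config = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE,
                         show_col_types = FALSE)
  if (!is.null(schema_config)) {
    for (canon in names(schema_config)) {
      from <- schema_config[[canon]]
      if (!from %in% names(raw)) {
        stop(sprintf("schema_config maps '%s' from missing column '%s'",
                     canon, from))
      }
      names(raw)[names(raw) == from] <- canon
    }
  }
  sch <- site_schema()
  missing_req <- setdiff(names(sch$required), names(raw))
  if (length(missing_req)) {
    stop("missing required column(s): ", paste(missing_req, collapse = ", "))
  }
  all_spec <- c(sch$required, sch$optional)
  out <- raw
  for (nm in names(raw)) {
    if (nm %in% names(all_spec)) {
      out[[nm]] <- parse_schema_column(raw[[nm]], nm, all_spec[[nm]])
    }
  }
  hard <- validate_dataset(out, severity = "error")
  if (nrow(hard)) {
    stop("invalid site table:\n",
         paste(sprintf("  [%s] %s: %s", hard$site_id, hard$field,
                       hard$message), collapse = "\n"))
  }
  as_tibble(out)
}

#' Write a site table
#'
#' Inverse of [read_site_table()]: missing values become empty cells so the
#' read/write round trip is the identity.
#'
#' @param sites tibble of sites
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_site_table <- function(sites, path) {
  readr::write_csv(sites, path, na = "")
  invisible(path)
}

#' Validate a parsed site table
#'
#' Returns a per-record issue report rather than failing. Severity "error"
#' marks violated invariants (impossible values, violated flux identities);
#' severity "warning" flags values outside biome plausibility windows
#' (NEP in \[-500, 1200\], Reco in \[200, 4000\], GPP in \[300, 4500\]
#' gC m-2 y-1, for both EC and BM where present).
#'
#' @param sites parsed site table
#' @param severity restrict the report to "error" or "warning" rows
#' @param partition_tol tolerance (gC m-2 y-1) for the soil-respiration
#'   partition identity Rsoil = Rroot + Rh-soil
#' @return tibble with columns site_id, severity, field, message
#' @export
validate_dataset <- function(sites, severity = c("all", "error", "warning"),
                             partition_tol = 1) {
  severity <- match.arg(severity)
  issues <- list()
  add <- function(site_id, sev, field, message) {
    issues[[length(issues) + 1]] <<- tibble(
      site_id = site_id, severity = sev, field = field, message = message)
  }
  has <- function(nm) nm %in% names(sites)
  n <- nrow(sites)
  for (i in seq_len(n)) {
    id <- as.character(sites$site_id[i])
    get <- function(nm) if (has(nm)) sites[[nm]][i] else NA

    lat <- get("latitude")
    if (!is.na(lat) && abs(lat) > 90) {
      add(id, "error", "latitude", "latitude outside [-90, 90]")
    }
    ym <- get("years_measured")
    if (!is.na(ym) && ym < 1) {
      add(id, "error", "years_measured", "years_measured must be >= 1")
    }
    lai <- get("lai")
    if (!is.na(lai) && lai < 0) add(id, "error", "lai", "lai must be >= 0")

    # non-negative component fluxes
    for (nm in intersect(bm_component_fields(), names(sites))) {
      v <- sites[[nm]][i]
      if (!is.na(v) && v < 0) {
        add(id, "error", nm, "component flux must be >= 0")
      }
    }

    # soil-respiration partition identity
    rs <- get("rsoil"); rr <- get("rroot"); rh <- get("rh_soil")
    if (!is.na(rs) && !is.na(rr) && !is.na(rh)) {
      gap <- rs - (rr + rh)
      if (abs(gap) > partition_tol) {
        add(id, "error", "rsoil",
            sprintf("rsoil != rroot + rh_soil (off by %.1f)", gap))
      }
    } else if (!is.na(rs) && !is.na(rr) && rs < rr) {
      add(id, "error", "rsoil", "rsoil < rroot: partition impossible")
    } else if (!is.na(rs) && !is.na(rh) && rs < rh) {
      add(id, "error", "rsoil", "rsoil < rh_soil: partition impossible")
    }

    # CO2 scrubbing only defined for NSF chamber systems
    scr <- get("co2_scrubbing"); cham <- get("soil_chamber")
    if (isTRUE(scr) && (is.na(cham) || cham != "NSF")) {
      add(id, "error", "co2_scrubbing",
          "co2_scrubbing may be set only for NSF chamber systems")
    }

    # plausibility windows (EC and BM fluxes)
    windows <- list(
      nep_ec = c(-500, 1200), reco_ec = c(200, 4000), gpp_ec = c(300, 4500))
    for (nm in names(windows)) {
      v <- get(nm)
      w <- windows[[nm]]
      if (!is.na(v) && (v < w[1] || v > w[2])) {
        add(id, "warning", nm,
            sprintf("%s = %.0f outside plausibility window [%g, %g]",
                    nm, v, w[1], w[2]))
      }
    }
    if (!is.na(get("reco_ec")) && get("reco_ec") <= 0) {
      add(id, "error", "reco_ec", "Reco must be > 0")
    }
    if (!is.na(get("gpp_ec")) && get("gpp_ec") <= 0) {
      add(id, "error", "gpp_ec", "GPP must be > 0")
    }

    # stock inventories
    ts <- get("time_start"); te <- get("time_end")
    if (!is.na(ts) && !is.na(te) && te <= ts) {
      add(id, "error", "time_end", "time_end must exceed time_start")
    }
    for (nm in c("wood_stock_start", "wood_stock_end",
                 "soil_stock_start", "soil_stock_end")) {
      v <- get(nm)
      if (!is.na(v) && v < 0) add(id, "error", nm, "stock must be >= 0")
    }
  }
  rep <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble(site_id = character(), severity = character(),
           field = character(), message = character())
  if (severity != "all") rep <- rep[rep$severity == severity, , drop = FALSE]
  rep
}

#' Serialize a validation report to JSON
#'
#' @param report tibble from [validate_dataset()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}
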