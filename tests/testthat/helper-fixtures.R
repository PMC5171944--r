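# shared fixtures built in code

# minimal two-site table covering required columns plus a few components
fixture_site_tbl <- function() {
  tibble::tibble(
    site_id = c("A", "B"),
    latitude = c(48.0, 61.5),
    longitude = c(7.8, 24.3),
    climate_zone = c("temperate", "boreal"),
    years_measured = c(2L, 1L),
    data_quality = c("high", "fair"),
    nep_ec = c(450, 120),
    reco_ec = c(1200, 800),
    gpp_ec = c(1650, 920),
    ec_partitioning = c("nighttime", "daytime"),
    npp_wood_aboveground = c(300, 150),
    npp_foliage = c(150, 90),
    npp_fineroot = c(120, 60),
    ra_leaf = c(250, 180),
    ra_wood = c(150, 90),
    rsoil = c(650, 420),
    rroot = c(300, 180),
    rh_soil = c(350, 240),
    rh_cwd = c(50, NA),
    soil_chamber = c("NSF", "NSNF"),
    co2_scrubbing = c(TRUE, NA),
    light_inhibition_considered = c(TRUE, FALSE),
    rleaf_parameterization = c("site_specific", "generic"),
    lai = c(5.2, 2.4)
  )
}

write_fixture_csv <- function(tbl = fixture_site_tbl(),
                              path = tempfile(fileext = ".csv")) {
  readr::write_csv(tbl, path, na = "")
  path
}

# random biometric component sets satisfying the soil partition identity
random_components <- function(n) {
  tibble::tibble(
    npp_wood_aboveground = stats::runif(n, 100, 600),
    npp_foliage = stats::runif(n, 50, 400),
    npp_fineroot = stats::runif(n, 30, 300),
    npp_coarseroot = stats::runif(n, 0, 120),
    ra_leaf = stats::runif(n, 100, 600),
    ra_wood = stats::runif(n, 50, 400),
    ra_understory = stats::runif(n, 0, 60),
    rroot = stats::runif(n, 100, 700),
    rh_soil = stats::runif(n, 100, 900),
    rh_cwd = stats::runif(n, 0, 120)
  ) |>
    dplyr::mutate(rsoil = rroot + rh_soil)
}
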