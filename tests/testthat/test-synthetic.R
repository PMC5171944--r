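zero_noise_cfg <- function(...) {
  args <- utils::modifyList(
    list(cv_ec = 0, cv_bm = 0, nep_bm_offset = 0,
         npp_missing_fraction = 0, rleaf_overestimate_no_li = 0,
         nsnf_rsoil_underestimate = 0, cv_partition = 0,
         stock_noise_sd = 0),
    list(...))
  do.call(sim_config, args)
}

test_that("generation is reproducible from the seed", {
  d1 <- generate_dataset(sim_config(seed = 5))
  d2 <- generate_dataset(sim_config(seed = 5))
  expect_identical(d1, d2)
  d3 <- generate_dataset(sim_config(seed = 6))
  expect_false(identical(d1$sites$nep_ec, d3$sites$nep_ec))
})

test_that("zone structure follows the configuration", {
  d <- generate_dataset(sim_config(seed = 2))
  counts <- vapply(c("boreal", "temperate", "tropical"), function(z) {
    sum(d$sites$climate_zone == z)
  }, integer(1))
  expect_equal(unname(counts), c(6L, 22L, 3L))
  expect_true(all(abs(d$sites$latitude[
    d$sites$climate_zone == "tropical"]) < 23.5))
})

test_that("generated truth satisfies the budget identities exactly", {
  d <- generate_dataset(sim_config(seed = 3))
  t <- d$truth
  expect_equal(t$gpp - t$reco, t$nep, tolerance = 1e-12)
  expect_equal(t$npp - t$rh, t$nep, tolerance = 1e-9)
  expect_equal(t$reco, t$ra + t$rh, tolerance = 1e-12)
  expect_equal(t$rsoil, t$rroot + t$rh_soil, tolerance = 1e-12)
  # observed BM components keep the soil partition identity
  expect_equal(d$sites$rsoil, d$sites$rroot + d$sites$rh_soil,
               tolerance = 1e-12)
})

test_that("generated tables pass schema validation and round-trip", {
  d <- generate_dataset(sim_config(seed = 4))
  rep <- validate_dataset(d$sites)
  expect_false(any(rep$severity == "error"))
  path <- tempfile(fileext = ".csv")
  write_site_table(d$sites, path)
  back <- read_site_table(path)
  expect_equal(back$nep_ec, d$sites$nep_ec, tolerance = 1e-9)
  expect_identical(back$soil_chamber, d$sites$soil_chamber)
})

test_that("zero noise and zero bias give exact convergence", {
  d <- generate_dataset(zero_noise_cfg(seed = 10))
  bud <- assemble_bm_budget(d$sites)
  expect_equal(max(abs(d$sites$nep_ec - bud$nep_bm)), 0, tolerance = 1e-8)
  expect_equal(max(abs(d$sites$reco_ec - bud$reco_bm)), 0,
               tolerance = 1e-8)
  expect_equal(max(abs(d$sites$gpp_ec - bud$gpp_bm)), 0, tolerance = 1e-8)
  fit <- ma_regression(d$sites$nep_ec, bud$nep_bm)
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("the biometric NEP offset moves the observed difference", {
  d0 <- generate_dataset(zero_noise_cfg(seed = 20))
  dm <- generate_dataset(zero_noise_cfg(seed = 20, nep_bm_offset = -100))
  b0 <- assemble_bm_budget(d0$sites)
  bm <- assemble_bm_budget(dm$sites)
  expect_equal(mean(dm$sites$nep_ec - bm$nep_bm) -
                 mean(d0$sites$nep_ec - b0$nep_bm), 100, tolerance = 1e-6)
})

test_that("Reco divergence grows with the leaf-respiration inflation", {
  rds <- vapply(c(0, 0.2, 0.4), function(ov) {
    cfg <- zero_noise_cfg(seed = 30, rleaf_overestimate_no_li = ov)
    d <- generate_dataset(cfg)
    bud <- assemble_bm_budget(d$sites)
    mean(relative_difference(bud$reco_bm, d$sites$reco_ec, "Reco"))
  }, numeric(1))
  expect_equal(rds[1], 0, tolerance = 1e-9)
  expect_true(all(diff(rds) > 0))
})

test_that("chamber underestimate can cancel leaf inflation at NSNF sites", {
  # 20% Rleaf inflation (~28% of Reco) vs 10% Rsoil deficit (~55% of Reco)
  cfg <- zero_noise_cfg(seed = 40, rleaf_overestimate_no_li = 0.20,
                        nsnf_rsoil_underestimate = 0.10)
  d <- generate_dataset(cfg)
  bud <- assemble_bm_budget(d$sites)
  rd <- relative_difference(bud$reco_bm, d$sites$reco_ec, "Reco")
  nsnf <- d$sites$soil_chamber == "NSNF"
  nli <- !d$sites$light_inhibition_considered
  # NSNF sites neglecting light inhibition: the two errors compensate
  expect_lt(abs(mean(rd[nsnf & nli])), 0.03)
  # NSF sites neglecting light inhibition: inflation stands
  expect_gt(mean(rd[d$sites$soil_chamber == "NSF" & nli]), 0.03)
})

test_that("recovery report is unbiased under a zero-bias configuration", {
  cfg <- sim_config(cv_ec = 0.05, cv_bm = 0.05,
                    rleaf_overestimate_no_li = 0,
                    nsnf_rsoil_underestimate = 0, seed = 100)
  rec <- recovery_report(cfg, n_replicates = 50)
  nep <- rec[rec$statistic == "nep_diff_ec_minus_bm", ]
  expect_lt(abs(nep$bias), 3 * nep$sd_estimate / sqrt(50))
  expect_gt(nep$coverage, 0.85)
  # EC NEP noise exceeds the assembled-BM noise, so the major-axis slope
  # attenuates somewhat below 1 even without bias
  slope <- rec[rec$statistic == "ma_slope_nep", ]
  expect_gt(slope$mean_estimate, 0.7)
  expect_lt(slope$mean_estimate, 1.1)
})

test_that("impossible share configurations are rejected", {
  expect_error(sim_config(npp_shares = c(foliage = 0.5, wood = 0.5,
                                         root = 0.3, other = 0.2)))
  expect_error(sim_config(npp_missing_fraction = 1.2))
})
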