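test_that("soil-respiration partition completes the missing member", {
  expect_equal(partition_rsoil(650, 300, NA)$rh_soil, 350)
  expect_equal(partition_rsoil(650, NA, 350)$rroot, 300)
  expect_equal(partition_rsoil(NA, 300, 350)$rsoil, 650)
  expect_equal(partition_rsoil(800, 0, NA)$rh_soil, 800)
  expect_error(partition_rsoil(200, 300, NA), "negative|inconsistent")
  expect_error(partition_rsoil(650, NA, NA), "at least two")
  expect_error(partition_rsoil(650, 300, 300), "inconsistent")
  # within tolerance, all three present is accepted
  expect_silent(partition_rsoil(650, 300, 350.5))
})

test_that("biometric budget matches the hand-worked example", {
  comp <- tibble::tibble(
    npp_wood_aboveground = 300, npp_foliage = 150, npp_fineroot = 50,
    ra_leaf = 250, ra_wood = 150, rroot = 300, rh_soil = 350, rh_cwd = 50)
  b <- assemble_bm_budget(comp)
  expect_equal(b$npp_total, 500)
  expect_equal(b$nep_bm, 100)
  expect_equal(b$reco_bm, 1100)
  expect_equal(b$gpp_bm, 1200)
  expect_equal(b$gpp_bm - b$reco_bm, b$nep_bm)
})

test_that("budget handles zero components and missing rh_cwd", {
  comp0 <- tibble::tibble(
    npp_wood_aboveground = 0, npp_foliage = 0, npp_fineroot = 0,
    ra_leaf = 0, ra_wood = 0, rroot = 0, rh_soil = 0, rh_cwd = 0)
  b0 <- assemble_bm_budget(comp0)
  expect_equal(c(b0$nep_bm, b0$reco_bm, b0$gpp_bm), c(0, 0, 0))

  comp <- tibble::tibble(
    npp_wood_aboveground = 300, npp_foliage = 150, npp_fineroot = 50,
    ra_leaf = 250, ra_wood = 150, rroot = 300, rh_soil = 350)
  b <- assemble_bm_budget(comp)
  expect_equal(b$nep_bm, 500 - 350)
  expect_match(b$completeness_flags, "rh_cwd_omitted")
})

test_that("fluxes with unmet preconditions are NA, others returned", {
  comp <- tibble::tibble(
    npp_wood_aboveground = 300, npp_foliage = 150, npp_fineroot = 50,
    ra_leaf = 250, ra_wood = 150, rsoil = 650)  # no partition available
  b <- assemble_bm_budget(comp)
  expect_true(is.na(b$nep_bm))   # needs rh_soil
  expect_true(is.na(b$gpp_bm))   # needs rroot
  expect_equal(b$reco_bm, 250 + 150 + 650)
  expect_match(b$completeness_flags, "rsoil_partition_unavailable")
})

test_that("budget closure and additivity hold on random components", {
  set.seed(11)
  comp <- random_components(200)
  b <- assemble_bm_budget(comp)
  expect_true(all(abs(b$gpp_bm - b$reco_bm - b$nep_bm) < 1e-9))
  b2 <- assemble_bm_budget(comp * 2.5)
  expect_equal(b2$nep_bm, 2.5 * b$nep_bm, tolerance = 1e-12)
  expect_equal(b2$gpp_bm, 2.5 * b$gpp_bm, tolerance = 1e-12)
})

test_that("stock-inventory NEP matches hand arithmetic and sign", {
  inv <- data.frame(time_start = 2000, time_end = 2002,
                    wood_stock_start = 10000, wood_stock_end = 10300,
                    soil_stock_start = 5000, soil_stock_end = 5050,
                    lateral_losses = 25)
  expect_equal(nep_from_stocks(inv), 350 / 2 + 25)
  inv2 <- within(inv, {
    wood_stock_end <- wood_stock_start; soil_stock_end <- soil_stock_start
    lateral_losses <- 0
  })
  expect_equal(nep_from_stocks(inv2), 0)
  inv3 <- within(inv, {
    time_end <- 2001; wood_stock_end <- wood_stock_start - 100
    soil_stock_end <- soil_stock_start; lateral_losses <- 0
  })
  expect_equal(nep_from_stocks(inv3), -100)
  inv4 <- within(inv, time_end <- time_start)
  expect_error(nep_from_stocks(inv4), "exceed")
})

test_that("relative difference is antisymmetric, bounded, NEP-refusing", {
  expect_equal(relative_difference(115, 100, "GPP"), 15 / 107.5)
  expect_equal(relative_difference(840, 840, "Reco"), 0)
  set.seed(3)
  a <- runif(50, 10, 4000); b <- runif(50, 10, 4000)
  rd <- relative_difference(a, b, "Reco")
  expect_true(all(rd > -2 & rd < 2))
  expect_equal(rd, -relative_difference(b, a, "Reco"))
  expect_error(relative_difference(100, 50, "NEP"), "unsupported|undefined")
})

test_that("composition shares match hand arithmetic and sum to one", {
  comp <- tibble::tibble(
    npp_wood_aboveground = c(340, 340), npp_foliage = c(300, 300),
    npp_fineroot = c(210, 210), npp_coarseroot = c(90, 90),
    npp_understory = c(40, 40), npp_reproductive = c(20, 20),
    ra_leaf = c(280, 280), ra_wood = c(150, 150),
    rroot = c(250, 250), rh_soil = c(300, 300), rh_cwd = c(20, 20)) |>
    dplyr::mutate(rsoil = rroot + rh_soil)
  cs <- composition_summary(comp)
  reco <- cs[cs$partition == "reco", ]
  expect_equal(reco$mean_share[match(c("rsoil", "rleaf", "rwood", "rh_cwd"),
                                     reco$component)],
               c(550, 280, 150, 20) / 1000)
  expect_true(all(cs$sem_share == 0))  # identical sites
  for (p in unique(cs$partition[cs$partition != "root_npp"])) {
    expect_equal(sum(cs$mean_share[cs$partition == p]), 1,
                 tolerance = 1e-9)
  }
  expect_equal(cs$mean_share[cs$partition == "root_npp"], 210 / 300)
  expect_error(composition_summary(comp[1, ]), "two sites")
})
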