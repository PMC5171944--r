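test_that("site table round-trips through write and read", {
  tbl <- fixture_site_tbl()
  path <- write_fixture_csv(tbl)
  got <- read_site_table(path)
  expect_equal(nrow(got), 2)
  for (nm in names(tbl)) {
    if (is.numeric(tbl[[nm]])) {
      expect_equal(got[[nm]], as.numeric(tbl[[nm]]), tolerance = 1e-9)
    } else {
      expect_identical(as.character(got[[nm]]), as.character(tbl[[nm]]))
    }
  }
  # second pass: write the parsed table and read again, bit-stable
  path2 <- tempfile(fileext = ".csv")
  write_site_table(got, path2)
  expect_equal(read_site_table(path2), got, tolerance = 1e-12)
})

test_that("missing required columns are named in the error", {
  tbl <- fixture_site_tbl()
  tbl$nep_ec <- NULL
  expect_error(read_site_table(write_fixture_csv(tbl)), "nep_ec")
})

test_that("schema_config remaps nonstandard column names", {
  tbl <- fixture_site_tbl()
  names(tbl)[names(tbl) == "nep_ec"] <- "NEP_tower"
  got <- read_site_table(write_fixture_csv(tbl),
                         schema_config = c(nep_ec = "NEP_tower"))
  expect_equal(got$nep_ec, c(450, 120))
})

test_that("enum levels are validated case-insensitively", {
  tbl <- fixture_site_tbl()
  tbl$climate_zone <- c("Temperate", "BOREAL")
  got <- read_site_table(write_fixture_csv(tbl))
  expect_identical(got$climate_zone, c("temperate", "boreal"))

  tbl$climate_zone <- c("temperate", "alpine")
  expect_error(read_site_table(write_fixture_csv(tbl)), "alpine")
})

test_that("unparseable numerics report the row index", {
  tbl <- fixture_site_tbl()
  tbl$nep_ec <- c("450", "oops")
  expect_error(read_site_table(write_fixture_csv(tbl)), "row\\(s\\) 2")
})

test_that("violated soil-respiration partition is a hard error", {
  tbl <- fixture_site_tbl()
  tbl$rsoil[1] <- 650; tbl$rroot[1] <- 300; tbl$rh_soil[1] <- 300
  expect_error(read_site_table(write_fixture_csv(tbl)), "rsoil")
})

test_that("unknown extra columns are preserved", {
  tbl <- fixture_site_tbl()
  tbl$my_note <- c("x", "y")
  got <- read_site_table(write_fixture_csv(tbl))
  expect_identical(got$my_note, c("x", "y"))
})

test_that("validate_dataset flags implausible fluxes as warnings only", {
  tbl <- fixture_site_tbl()
  rep0 <- validate_dataset(tbl)
  expect_equal(nrow(rep0), 0)

  tbl$nep_ec[1] <- 2000
  rep1 <- validate_dataset(tbl)
  expect_equal(nrow(rep1), 1)
  expect_identical(rep1$severity, "warning")
  expect_identical(rep1$field, "nep_ec")

  # rsoil below rroot with rh_soil absent: partition impossible -> error
  tbl2 <- fixture_site_tbl()
  tbl2$rh_soil <- NA_real_
  tbl2$rsoil[1] <- 200; tbl2$rroot[1] <- 300
  rep2 <- validate_dataset(tbl2)
  expect_true(any(rep2$severity == "error" & rep2$site_id == "A"))
})

test_that("co2 scrubbing is only valid for NSF chamber systems", {
  tbl <- fixture_site_tbl()
  tbl$soil_chamber[1] <- "NSNF"   # but co2_scrubbing stays TRUE
  rep <- validate_dataset(tbl)
  expect_true(any(rep$field == "co2_scrubbing" & rep$severity == "error"))
})

test_that("every methodological variant has exactly one profile field", {
  expect_length(method_profile_fields(), 20)  # 17 BM + EC + 2 NPP flags
  expect_false(any(duplicated(method_profile_fields())))
  sch <- fluxconverge:::site_schema()
  all_cols <- c(names(sch$required), names(sch$optional))
  expect_true(all(method_profile_fields() %in% all_cols))
})

test_that("validation report serializes to JSON records", {
  tbl <- fixture_site_tbl()
  tbl$nep_ec[1] <- 2000
  path <- tempfile(fileext = ".json")
  write_validation_report(validate_dataset(tbl), path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(names(back), c("site_id", "severity", "field", "message"))
})
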