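# registry_core: outcome classification, analysis-set accounting,
# derived covariates, validation, CSV round trip.

test_that("delivery-outcome classification applies GA-first stillbirth rule", {
  rec <- make_records(
    7,
    outcome_status = c("fetal_death", "fetal_death", "fetal_death",
                       "fetal_death", "fetal_death", "live_birth",
                       "termination"),
    ga_weeks = c(28, NA, 20, 19, NA, 39, 12),
    birthweight_g = c(1200, 450, 400, 900, NA, 3100, NA)
  )
  out <- classify_delivery_outcome(rec)
  expect_identical(out, c(
    "stillbirth",   # ga 28 >= 20
    "miscarriage",  # ga missing, 450 g below fallback
    "stillbirth",   # ga 20 decides; 400 g fallback never consulted
    "miscarriage",  # ga 19 decides even though bw 900 >= 500 (GA-first)
    "miscarriage",  # both missing
    "live_birth", "termination"))
})

test_that("weight fallback threshold and strict_gt_500g switch", {
  rec <- make_records(2, outcome_status = "fetal_death",
                      ga_weeks = NA_real_, birthweight_g = c(500, 501))
  expect_identical(classify_delivery_outcome(rec),
                   c("stillbirth", "stillbirth"))
  strict <- outcome_thresholds(strict_gt_500g = TRUE)
  expect_identical(classify_delivery_outcome(rec, strict),
                   c("miscarriage", "stillbirth"))
})

test_that("classification is total and single-valued over a boundary grid", {
  grid <- expand.grid(
    outcome_status = c("fetal_death", "live_birth", "miscarriage",
                       "termination", "missing"),
    ga_weeks = c(NA, 10, 19, 20, 32, 50),
    birthweight_g = c(NA, 100, 499, 500, 3000),
    stringsAsFactors = FALSE)
  rec <- make_records(nrow(grid), outcome_status = grid$outcome_status,
                      ga_weeks = grid$ga_weeks,
                      birthweight_g = grid$birthweight_g)
  out <- classify_delivery_outcome(rec)
  expect_true(all(out %in% c("stillbirth", "live_birth", "miscarriage",
                             "termination", "missing")))
  expect_length(out, nrow(grid))
  # deterministic
  expect_identical(out, classify_delivery_outcome(rec))
})

test_that("negative measurements are rejected with record ids", {
  rec <- make_records(2, outcome_status = "fetal_death",
                      ga_weeks = c(-1, 30))
  expect_error(classify_delivery_outcome(rec), "t0001")
})

test_that("analysis set accounting mirrors the enrollment diagram", {
  rec <- make_records(
    10,
    outcome_status = c(rep("live_birth", 7), "fetal_death", "miscarriage",
                       "missing"),
    ga_weeks = c(rep(39, 7), 28, 12, NA),
    birthweight_g = c(rep(3100, 7), 1200, NA, NA))
  aset <- build_analysis_set(rec)
  expect_equal(aset$counts$included, 8)
  expect_equal(aset$counts$excluded_by_reason,
               list(miscarriage = 1L, termination = 0L, missing = 1L))
  # partition: included + excluded = enrolled
  expect_equal(aset$counts$included +
                 sum(unlist(aset$counts$excluded_by_reason)),
               aset$counts$enrolled)
  expect_true(all(aset$records$outcome %in% c("live_birth", "stillbirth")))

  # degenerate inputs
  empty <- build_analysis_set(make_records(0))
  expect_equal(empty$counts$included, 0)
  allmc <- build_analysis_set(make_records(3, outcome_status = "miscarriage",
                                           ga_weeks = 12,
                                           birthweight_g = NA))
  expect_equal(allmc$counts$included, 0)
  est <- stillbirth_rate(0, allmc$counts$included)
  expect_true(est$undefined)
})

test_that("analysis-set counts match generator truth on a large registry", {
  cfg <- lean_config(n_clusters = 20, births = 5000, rate = 0.03,
                     exclusions = list(miscarriage = 0.02,
                                       termination = 0.001,
                                       missing = 0.005))
  reg <- generate_registry(cfg, seed = 11)   # 100,000 enrolled
  expect_equal(reg$truth$counts$enrolled, 100000L)
  aset <- build_analysis_set(reg$records)
  expect_equal(aset$counts$included, reg$truth$counts$included)
  expect_equal(aset$counts$excluded_by_reason$miscarriage,
               reg$truth$counts$miscarriage)
  expect_equal(aset$counts$excluded_by_reason$termination,
               reg$truth$counts$termination)
  expect_equal(aset$counts$excluded_by_reason$missing,
               reg$truth$counts$missing)
  expect_equal(sum(aset$records$outcome == "stillbirth"),
               reg$truth$counts$stillbirths)
})

test_that("covariate groupings respect the table boundaries", {
  rec <- make_records(2, ga_weeks = c(36, 37))
  cov <- derive_covariates(rec)
  expect_identical(cov$preterm, c(TRUE, FALSE))

  rec <- make_records(4, maternal_age = c(19, 20, 35, 36))
  expect_identical(derive_covariates(rec)$age_group,
                   c("lt20", "20_35", "20_35", "gt35"))

  rec <- make_records(4, anc_visits = c(0, 1, 2, 3))
  expect_identical(derive_covariates(rec)$anc_group,
                   c("0", "1_2", "1_2", "ge3"))

  rec <- make_records(4, parity = c(0, 1, 2, 3))
  expect_identical(derive_covariates(rec)$parity_group,
                   c("0", "1_2", "1_2", "gt2"))

  rec <- make_records(2, birthweight_g = c(2499, 2500))
  expect_identical(derive_covariates(rec)$low_birthweight, c(TRUE, FALSE))
})

test_that("covariate groupings are exhaustive and non-overlapping", {
  # every integer in the source domain lands in exactly one group
  ages <- 10:60
  grp <- derive_covariates(make_records(length(ages),
                                        maternal_age = ages))$age_group
  expect_false(anyNA(grp))
  anc <- 0:20
  grp <- derive_covariates(make_records(length(anc),
                                        anc_visits = anc))$anc_group
  expect_false(anyNA(grp))
  par <- 0:15
  grp <- derive_covariates(make_records(length(par),
                                        parity = par))$parity_group
  expect_false(anyNA(grp))
})

test_that("missing source fields yield missing covariates, never errors", {
  rec <- make_records(1, ga_weeks = NA_real_, maternal_age = NA_real_,
                      anc_visits = NA_real_, parity = NA_real_,
                      prior_pregnancy_live = "unknown",
                      presentation = "unknown", sex = "unknown")
  cov <- derive_covariates(rec)
  expect_true(is.na(cov$preterm))
  expect_true(is.na(cov$age_group))
  expect_true(is.na(cov$anc_group))
  expect_true(is.na(cov$parity_group))
  expect_true(is.na(cov$prior_loss))
  expect_true(is.na(cov$breech))
  expect_true(is.na(cov$sex))
})

test_that("validation rejects out-of-range rows with logged reasons", {
  rec <- make_records(5)
  rec$ga_weeks[1] <- 55
  rec$birthweight_g[2] <- 50
  rec$year[3] <- 2009
  rec$anc_visits[4] <- -1
  suppressMessages(clean <- validate_registry(rec))
  rejected <- attr(clean, "rejected")
  expect_equal(nrow(clean), 1)
  expect_setequal(rejected$record_id, c("t0001", "t0002", "t0003",
                                        "t0004"))
  expect_true(any(grepl("ga_weeks", rejected$reason)))
  expect_true(any(grepl("birthweight_g", rejected$reason)))
})

test_that("registry CSV round trip preserves records", {
  cfg <- lean_config(n_clusters = 3, births = 40,
                     covariates = default_synthetic_covariates(),
                     exclusions = list(miscarriage = 0.02,
                                       termination = 0.002,
                                       missing = 0.005))
  reg <- generate_registry(cfg, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg, path)
  back <- read_registry(path)
  expect_equal(nrow(attr(back, "rejected")), 0)
  expect_equal(back, reg$records[registry_columns()],
               ignore_attr = TRUE)
})
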