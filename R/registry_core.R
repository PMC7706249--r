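# Registry data model: schema, validation, delivery-outcome classification,
# analysis-set construction and derived covariates.

#' Site labels used by the registry
#'
#' Seven research sites grouped into one Latin-American, three African and
#' three south-Asian catchments.
#' @return character vector of site codes.
#' @export
registry_sites <- function() {
  c("guatemala", "drc", "zambia", "kenya", "belagavi", "nagpur", "pakistan")
}

#' @rdname registry_sites
#' @export
african_sites <- function() c("drc", "zambia", "kenya")

#' @rdname registry_sites
#' @export
asian_sites <- function() c("belagavi", "nagpur", "pakistan")

#' Names of the binary clinical condition flags
#'
#' Tri-state (`"true"`, `"false"`, `"unknown"`) per-record flags consumed by
#' the cause-of-stillbirth hierarchy and the maternal-condition cross-tab.
#' @return character vector of flag column names.
#' @export
condition_flags <- function() {
  c("trauma", "major_anomaly", "maternal_infection", "fetal_infection",
    "hypertensive_disease", "antepartum_hemorrhage",
    "obstructed_prolonged_labor", "breech_transverse",
    "other_asphyxia_condition")
}

#' Registry column order and schema
#'
#' One row per enrolled pregnancy/birth. Missing values are empty CSV
#' fields; enumerations are lowercase snake-case strings.
#'
#' @return `registry_columns()`: character vector of column names.
#'   `registry_schema()`: named list describing each column's type and
#'   allowed values (serialisable to JSON).
#' @export
registry_columns <- function() {
  c("record_id", "site", "cluster_id", "year", "maternal_age", "education",
    "parity", "prior_pregnancy_live", "anc_visits", "attendant", "location",
    "mode", "outcome_status", "ga_weeks", "birthweight_g", "sex", "multiple",
    "presentation", "maceration", condition_flags())
}

#' @rdname registry_columns
#' @export
registry_schema <- function() {
  flag <- list(type = "enum", values = c("true", "false", "unknown"))
  sch <- list(
    record_id = list(type = "string"),
    site = list(type = "enum", values = registry_sites()),
    cluster_id = list(type = "string"),
    year = list(type = "integer", min = 2010, max = 2018),
    maternal_age = list(type = "number", optional = TRUE),
    education = list(type = "enum", optional = TRUE,
                     values = c("none", "primary", "secondary",
                                "university_plus")),
    parity = list(type = "integer", min = 0, optional = TRUE),
    prior_pregnancy_live = list(type = "enum",
                                values = c("yes", "no", "unknown")),
    anc_visits = list(type = "integer", min = 0, optional = TRUE),
    attendant = list(type = "enum", optional = TRUE,
                     values = c("physician", "nurse_midwife_hw", "tba",
                                "family_other")),
    location = list(type = "enum", optional = TRUE,
                    values = c("hospital", "clinic", "home_other")),
    mode = list(type = "enum", optional = TRUE,
                values = c("vaginal", "vaginal_assisted", "cesarean")),
    outcome_status = list(type = "enum",
                          values = c("live_birth", "fetal_death",
                                     "miscarriage", "termination",
                                     "missing")),
    ga_weeks = list(type = "number", min = 10, max = 50, optional = TRUE),
    birthweight_g = list(type = "number", min = 100, max = 8000,
                         optional = TRUE),
    sex = list(type = "enum", values = c("male", "female", "unknown")),
    multiple = list(type = "enum", values = c("true", "false")),
    presentation = list(type = "enum",
                        values = c("cephalic", "breech_transverse",
                                   "unknown")),
    maceration = list(type = "enum",
                      values = c("macerated", "non_macerated", "unknown",
                                 "not_applicable"))
  )
  for (f in condition_flags()) sch[[f]] <- flag
  sch
}

#' Write the registry schema as a JSON document
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_registry_schema <- function(path) {
  jsonlite::write_json(registry_schema(), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

NUMERIC_COLUMNS <- c("year", "maternal_age", "parity", "anc_visits",
                     "ga_weeks", "birthweight_g")

#' Read a registry CSV
#'
#' Reads a one-row-per-birth CSV in the registry schema
#' ([registry_columns()]), converts numeric columns, and validates rows.
#' Rows violating hard invariants (out-of-range gestational age or
#' birthweight, negative counts, year outside 2010--2018, unknown site,
#' missing cluster) are dropped with a per-row reason, available as
#' `attr(x, "rejected")`.
#'
#' @param path path to a UTF-8 CSV with header.
#' @param validate drop invalid rows (default `TRUE`).
#' @return data.frame of clean records; attribute `rejected` holds a
#'   data.frame of `record_id`, `reason` for dropped rows.
#' @export
read_registry <- function(path, validate = TRUE) {
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = c("", "NA"), stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(registry_columns(), names(df))
  if (length(missing_cols) > 0)
    stop("registry CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[registry_columns()]
  for (col in NUMERIC_COLUMNS) {
    suppressWarnings(df[[col]] <- as.numeric(df[[col]]))
  }
  if (validate) df <- validate_registry(df)
  df
}

#' Validate registry records
#'
#' @param records data.frame in registry schema (numeric columns already
#'   numeric).
#' @return records passing validation, with rejected rows in
#'   `attr(, "rejected")`.
#' @export
validate_registry <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  flag_bad <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reason[bad & is.na(reason)] <<- why
  }
  flag_bad(!(records$site %in% registry_sites()), "unknown site")
  flag_bad(is.na(records$cluster_id) | records$cluster_id == "",
           "missing cluster_id")
  flag_bad(is.na(records$year) | records$year < 2010 | records$year > 2018,
           "year outside 2010-2018")
  ga <- records$ga_weeks
  flag_bad(!is.na(ga) & (ga < 10 | ga > 50), "ga_weeks outside [10, 50]")
  bw <- records$birthweight_g
  flag_bad(!is.na(bw) & (bw < 100 | bw > 8000),
           "birthweight_g outside [100, 8000]")
  flag_bad(!is.na(records$parity) & records$parity < 0, "negative parity")
  flag_bad(!is.na(records$anc_visits) & records$anc_visits < 0,
           "negative anc_visits")
  flag_bad(!(records$outcome_status %in%
               c("live_birth", "fetal_death", "miscarriage", "termination",
                 "missing")), "invalid outcome_status")

  bad <- !is.na(reason)
  rejected <- data.frame(record_id = records$record_id[bad],
                         reason = reason[bad], stringsAsFactors = FALSE)
  if (nrow(rejected) > 0) {
    message(nrow(rejected), " record(s) rejected at load time; ",
            "see attr(, 'rejected')")
  }
  out <- records[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Delivery-outcome thresholds
#'
#' The stillbirth definition is a modified WHO criterion: fetal death at
#' `>= ga_weeks` completed weeks of gestation or, when gestational age is
#' unavailable, birthweight `>= birthweight_g` grams. When both fields are
#' present the gestational-age criterion decides alone; the weight rule is
#' purely a fallback for missing gestational age.
#'
#' @param ga_weeks gestational-age threshold in completed weeks (default 20).
#' @param birthweight_g fallback birthweight threshold in grams (default
#'   500).
#' @param strict_gt_500g if `TRUE`, the weight fallback requires strictly
#'   `> birthweight_g` rather than `>=` (the denominators of some reports
#'   are described as "> 500 g"); default `FALSE` for internal consistency
#'   with the inclusion rule.
#' @return a list of class `outcome_thresholds`.
#' @export
outcome_thresholds <- function(ga_weeks = 20, birthweight_g = 500,
                               strict_gt_500g = FALSE) {
  structure(list(ga_weeks = ga_weeks, birthweight_g = birthweight_g,
                 strict_gt_500g = isTRUE(strict_gt_500g)),
            class = "outcome_thresholds")
}

#' Classify the delivery outcome of each record
#'
#' Applies the stillbirth/miscarriage rule to fetal deaths: gestational age
#' `>= 20` weeks is a stillbirth; when gestational age is missing,
#' birthweight `>= 500` g is a stillbirth; fetal deaths below the relevant
#' threshold (or with both fields missing) are miscarriages. Live births,
#' terminations and missing outcomes pass through unchanged.
#'
#' @param records data.frame with `outcome_status` and (optionally missing)
#'   `ga_weeks`, `birthweight_g`.
#' @param thresholds an [outcome_thresholds()] object.
#' @return character vector, one of `stillbirth`, `live_birth`,
#'   `miscarriage`, `termination`, `missing` per record.
#' @export
classify_delivery_outcome <- function(records,
                                      thresholds = outcome_thresholds()) {
  ga <- records$ga_weeks
  bw <- records$birthweight_g
  if (any(ga < 0, na.rm = TRUE) || any(bw < 0, na.rm = TRUE)) {
    bad <- which((!is.na(ga) & ga < 0) | (!is.na(bw) & bw < 0))
    stop("negative ga_weeks/birthweight_g for record(s): ",
         paste(utils::head(records$record_id[bad], 10), collapse = ", "),
         call. = FALSE)
  }
  out <- records$outcome_status
  out[is.na(out)] <- "missing"
  fd <- out == "fetal_death"
  ga_met <- !is.na(ga) & ga >= thresholds$ga_weeks
  bw_met <- if (thresholds$strict_gt_500g) {
    !is.na(bw) & bw > thresholds$birthweight_g
  } else {
    !is.na(bw) & bw >= thresholds$birthweight_g
  }
  # GA decides whenever present; the weight rule only fills in missing GA
  sb <- fd & (ga_met | (is.na(ga) & bw_met))
  out[fd] <- "miscarriage"
  out[sb] <- "stillbirth"
  out
}

#' Build the analysis set
#'
#' Applies the delivery-outcome classification and excludes miscarriages,
#' terminations of pregnancy and records with missing delivery outcome,
#' mirroring the enrollment-diagram accounting: screened, enrolled
#' (consented), excluded by reason, included.
#'
#' @param records validated registry data.frame (enrolled women).
#' @param n_screened number of women screened, if known; defaults to the
#'   number enrolled (consent fraction 100%).
#' @param thresholds an [outcome_thresholds()] object.
#' @return an object of class `analysis_set`: list with `records` (included
#'   rows plus an `outcome` column of `stillbirth`/`live_birth`) and
#'   `counts` (`screened`, `enrolled`, `excluded_by_reason`, `included`).
#' @export
build_analysis_set <- function(records, n_screened = NULL,
                               thresholds = outcome_thresholds()) {
  n_enrolled <- nrow(records)
  if (is.null(n_screened)) n_screened <- n_enrolled
  stopifnot_scalar_count(n_screened, "n_screened")
  outcome <- if (n_enrolled > 0) {
    classify_delivery_outcome(records, thresholds)
  } else {
    character(0)
  }
  included <- outcome %in% c("live_birth", "stillbirth")
  excluded_by_reason <- c(
    miscarriage = sum(outcome == "miscarriage"),
    termination = sum(outcome == "termination"),
    missing = sum(outcome == "missing")
  )
  recs <- records[included, , drop = FALSE]
  recs$outcome <- outcome[included]
  rownames(recs) <- NULL
  structure(list(
    records = recs,
    counts = list(screened = as.integer(n_screened),
                  enrolled = as.integer(n_enrolled),
                  excluded_by_reason = as.list(excluded_by_reason),
                  included = as.integer(sum(included)))
  ), class = "analysis_set")
}

#' @export
print.analysis_set <- function(x, ...) {
  cts <- x$counts
  cat("Analysis set\n")
  cat(sprintf("  screened:  %d\n", cts$screened))
  cat(sprintf("  enrolled:  %d (%.1f%% of screened)\n", cts$enrolled,
              ifelse(cts$screened > 0, 100 * cts$enrolled / cts$screened,
                     0)))
  ex <- unlist(cts$excluded_by_reason)
  cat(sprintf("  excluded:  %d (%s)\n", sum(ex),
              paste(names(ex), ex, sep = "=", collapse = ", ")))
  cat(sprintf("  included:  %d births (%d stillbirths)\n", cts$included,
              sum(x$records$outcome == "stillbirth")))
  invisible(x)
}

#' Enrollment ledger
#'
#' Flattens the analysis-set accounting into a serialisable ledger with
#' consent and inclusion percentages (half-up rounded to one decimal).
#'
#' @param aset an `analysis_set`.
#' @return named list suitable for JSON output.
#' @export
enrollment_ledger <- function(aset) {
  cts <- aset$counts
  list(
    screened = cts$screened,
    enrolled = cts$enrolled,
    consent_pct = pct_of(cts$enrolled, cts$screened),
    excluded_by_reason = cts$excluded_by_reason,
    excluded = sum(unlist(cts$excluded_by_reason)),
    included = cts$included,
    included_pct_of_enrolled = pct_of(cts$included, cts$enrolled),
    stillbirths = sum(aset$records$outcome == "stillbirth"),
    live_births = sum(aset$records$outcome == "live_birth")
  )
}

#' Derive the analysis covariates from registry fields
#'
#' Emits the categorical covariates used in the risk-factor tables:
#' preterm (`ga_weeks < 37`, WHO convention), low birthweight (`< 2500` g),
#' maternal age group (`lt20`, `20_35`, `gt35`), education, parity group
#' (`0`, `1_2`, `gt2`), prior-pregnancy-loss flag, antenatal-care-visit
#' group (`0`, `1_2`, `ge3`), birth attendant, delivery location, delivery
#' mode, multiple gestation, breech/transverse presentation and fetal sex.
#' Missing source fields yield missing covariates (each downstream table
#' drops missing rows, so denominators vary by row, matching registry
#' reporting practice); nothing is imputed.
#'
#' @param records data.frame of registry records (typically
#'   `analysis_set$records`).
#' @return data.frame keyed by `record_id` with one column per covariate.
#' @export
derive_covariates <- function(records) {
  ga <- records$ga_weeks
  bw <- records$birthweight_g
  age <- records$maternal_age
  parity <- records$parity
  anc <- records$anc_visits

  age_group <- rep(NA_character_, nrow(records))
  age_group[!is.na(age) & age < 20] <- "lt20"
  age_group[!is.na(age) & age >= 20 & age <= 35] <- "20_35"
  age_group[!is.na(age) & age > 35] <- "gt35"

  parity_group <- rep(NA_character_, nrow(records))
  parity_group[!is.na(parity) & parity == 0] <- "0"
  parity_group[!is.na(parity) & parity >= 1 & parity <= 2] <- "1_2"
  parity_group[!is.na(parity) & parity > 2] <- "gt2"

  anc_group <- rep(NA_character_, nrow(records))
  anc_group[!is.na(anc) & anc == 0] <- "0"
  anc_group[!is.na(anc) & anc >= 1 & anc <= 2] <- "1_2"
  anc_group[!is.na(anc) & anc >= 3] <- "ge3"

  prior <- records$prior_pregnancy_live
  prior_loss <- rep(NA, nrow(records))
  prior_loss[!is.na(prior) & prior == "no"] <- TRUE
  prior_loss[!is.na(prior) & prior == "yes"] <- FALSE

  pres <- records$presentation
  breech <- rep(NA, nrow(records))
  breech[!is.na(pres) & pres == "breech_transverse"] <- TRUE
  breech[!is.na(pres) & pres == "cephalic"] <- FALSE

  sex <- records$sex
  sex[!is.na(sex) & sex == "unknown"] <- NA

  data.frame(
    record_id = records$record_id,
    preterm = ifelse(is.na(ga), NA, ga < 37),
    low_birthweight = ifelse(is.na(bw), NA, bw < 2500),
    age_group = age_group,
    education = records$education,
    parity_group = parity_group,
    prior_loss = prior_loss,
    anc_group = anc_group,
    attendant = records$attendant,
    location = records$location,
    mode = records$mode,
    multiple = flag_as_logical(records$multiple),
    breech = breech,
    sex = sex,
    stringsAsFactors = FALSE
  )
}

#' Write the analysis set and its enrollment ledger
#'
#' @param aset an `analysis_set`.
#' @param csv_path output CSV (records + outcome + derived covariates).
#' @param ledger_path optional JSON path for the enrollment ledger.
#' @return `csv_path`, invisibly.
#' @export
write_analysis_set <- function(aset, csv_path, ledger_path = NULL) {
  cov <- derive_covariates(aset$records)
  out <- cbind(aset$records, cov[setdiff(names(cov), "record_id")])
  utils::write.csv(out, csv_path, row.names = FALSE, na = "")
  if (!is.null(ledger_path)) {
    jsonlite::write_json(enrollment_ledger(aset), ledger_path,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(csv_path)
}
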