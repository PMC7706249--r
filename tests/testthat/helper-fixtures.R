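# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# a registry data.frame with sensible defaults; override any field
make_records <- function(n = 1, ...) {
  overrides <- list(...)
  base <- list(
    record_id = sprintf("t%04d", seq_len(n)),
    site = "pakistan", cluster_id = "c01", year = 2015,
    maternal_age = 28, education = "primary", parity = 1,
    prior_pregnancy_live = "yes", anc_visits = 3, attendant = "physician",
    location = "hospital", mode = "vaginal",
    outcome_status = "live_birth", ga_weeks = 39, birthweight_g = 3100,
    sex = "female", multiple = "false", presentation = "cephalic",
    maceration = "not_applicable"
  )
  for (f in stillreg::condition_flags()) base[[f]] <- "false"
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  df <- as.data.frame(lapply(base, rep_len, n), stringsAsFactors = FALSE)
  df$record_id <- sprintf("t%04d", seq_len(n))
  for (nm in names(overrides))
    if (length(overrides[[nm]]) > 1 || nm == "record_id")
      df[[nm]] <- rep_len(overrides[[nm]], n)
  df
}

# flags data.frame for the cause classifier
make_flags <- function(n = 1, ...) {
  overrides <- list(...)
  base <- stats::setNames(
    rep(list("false"), length(stillreg::condition_flags())),
    stillreg::condition_flags())
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  as.data.frame(lapply(base, rep_len, n), stringsAsFactors = FALSE)
}

# one-site configuration used for fast generator tests
lean_config <- function(n_clusters = 10, births = 100, years = 2010,
                        rate = 0.03, trend = 1, cluster_sd = 0,
                        covariates = list(), exclusions = NULL, ...) {
  stillreg::synthetic_config(
    sites = list(stillreg::synthetic_site(
      "pakistan", n_clusters, births, years = years,
      stillbirth_rate = rate, yearly_trend = trend,
      cluster_sd = cluster_sd)),
    covariates = covariates,
    exclusions = exclusions %||%
      list(miscarriage = 0, termination = 0, missing = 0),
    ...
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force evaluation of the stated cause hierarchy, one
# record at a time (deliberately naive; the oracle for assign_cause)
oracle_cause <- function(flags_row, ga,
                         asphyxia = stillreg::default_asphyxia_conditions()) {
  on <- function(f) identical(flags_row[[f]], "true") ||
    isTRUE(flags_row[[f]])
  if (on("trauma")) return(list(cause = "trauma", rule = 1L))
  if (on("major_anomaly")) return(list(cause = "congenital_anomaly",
                                       rule = 2L))
  if (on("maternal_infection") || on("fetal_infection"))
    return(list(cause = "infection", rule = 3L))
  for (f in asphyxia) if (on(f)) return(list(cause = "asphyxia",
                                             rule = 4L))
  if (!is.na(ga) && ga < 32) return(list(cause = "prematurity",
                                         rule = 5L))
  list(cause = "unknown", rule = 6L)
}
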