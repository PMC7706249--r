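# Hierarchical cause-of-stillbirth classifier and the cause tabulations.
#
# The algorithm assigns exactly one primary cause per stillbirth by walking
# a fixed six-level hierarchy and returning the first level satisfied:
#   1. fetal trauma (accident)
#   2. major (visible) congenital anomaly
#   3. signs of maternal or fetal infection
#   4. any maternal/fetal condition associated with intrauterine asphyxia
#      (pre-eclampsia/eclampsia, antepartum hemorrhage, obstructed or
#      prolonged labor, plus a generic other-condition flag)
#   5. prematurity: gestational age < 32 completed weeks
#   6. unknown
# Unknown or missing condition flags count as absent; a stillbirth without
# a recorded gestational age can never be attributed to prematurity.

#' Cause labels in hierarchy order
#' @return character vector of the six causes.
#' @export
cause_levels <- function() {
  c("trauma", "congenital_anomaly", "infection", "asphyxia", "prematurity",
    "unknown")
}

#' Default asphyxia-associated condition set
#'
#' The conditions whose presence (at level 4) classifies a stillbirth as
#' asphyxia. The set is configurable because the source definition is
#' non-exhaustive ("including ..."); breech/transverse lie is deliberately
#' not in the default set — it is a reporting column, not part of the
#' stated algorithm.
#' @return character vector of flag names.
#' @export
default_asphyxia_conditions <- function() {
  c("hypertensive_disease", "antepartum_hemorrhage",
    "obstructed_prolonged_labor", "other_asphyxia_condition")
}

#' Assign a primary cause to each stillbirth
#'
#' @param records data.frame of stillbirth records carrying the condition
#'   flag columns ([condition_flags()]) and, unless `ga_weeks` is given
#'   separately, a `ga_weeks` column.
#' @param ga_weeks optional numeric vector overriding `records$ga_weeks`.
#' @param asphyxia_conditions character vector of flag names checked at
#'   hierarchy level 4; defaults to [default_asphyxia_conditions()].
#' @return data.frame with one row per input record: `cause` (factor over
#'   [cause_levels()]) and `rule_fired` (integer 1--6, the first satisfied
#'   level). If `records` has a `record_id` column it is carried through.
#' @examples
#' rec <- data.frame(trauma = "false", major_anomaly = "false",
#'                   maternal_infection = "false", fetal_infection = "false",
#'                   hypertensive_disease = "false",
#'                   antepartum_hemorrhage = "false",
#'                   obstructed_prolonged_labor = "true",
#'                   breech_transverse = "false",
#'                   other_asphyxia_condition = "false", ga_weeks = 36)
#' assign_cause(rec)  # asphyxia, rule 4
#' @export
assign_cause <- function(records, ga_weeks = NULL,
                         asphyxia_conditions = default_asphyxia_conditions()) {
  stopifnot(is.data.frame(records))
  bad <- setdiff(asphyxia_conditions, condition_flags())
  if (length(bad) > 0)
    stop("unknown asphyxia condition flag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(ga_weeks)) ga_weeks <- records$ga_weeks
  n <- nrow(records)
  if (is.null(ga_weeks)) ga_weeks <- rep(NA_real_, n)

  fl <- function(name) {
    if (name %in% names(records)) flag_as_logical(records[[name]])
    else rep(FALSE, n)
  }
  trauma <- fl("trauma")
  anomaly <- fl("major_anomaly")
  infection <- fl("maternal_infection") | fl("fetal_infection")
  asphyxia <- Reduce(`|`, lapply(asphyxia_conditions, fl), rep(FALSE, n))
  premature <- !is.na(ga_weeks) & ga_weeks < 32

  # assign lowest priority first so each later level overwrites: the final
  # value is the first satisfied level of the hierarchy
  cause <- rep("unknown", n)
  rule <- rep(6L, n)
  set <- function(which, label, lvl) {
    cause[which] <<- label
    rule[which] <<- lvl
  }
  set(premature, "prematurity", 5L)
  set(asphyxia, "asphyxia", 4L)
  set(infection, "infection", 3L)
  set(anomaly, "congenital_anomaly", 2L)
  set(trauma, "trauma", 1L)

  out <- data.frame(
    cause = factor(cause, levels = cause_levels()),
    rule_fired = rule,
    stringsAsFactors = FALSE
  )
  if ("record_id" %in% names(records))
    out <- cbind(record_id = records$record_id, out)
  out
}

as_cause_factor <- function(assignments) {
  cause <- if (is.data.frame(assignments)) assignments$cause else assignments
  factor(cause, levels = cause_levels())
}

#' Tabulate causes of stillbirth, optionally by stratum
#'
#' Counts and percentages per cause; percentages are computed on the
#' stratum total and rounded half-up to one decimal, matching report-table
#' style.
#'
#' @param assignments output of [assign_cause()], or a vector of causes.
#' @param strata optional stratum labels (e.g. site), same length as
#'   `assignments`; `NULL` for a single overall column.
#' @return data.frame of class `cause_table` with columns `stratum`,
#'   `cause`, `n`, `pct` and attribute `totals` (named stratum sizes).
#' @export
tabulate_causes <- function(assignments, strata = NULL) {
  cause <- as_cause_factor(assignments)
  if (is.null(strata)) strata <- rep("total", length(cause))
  strata <- as.factor(strata)
  counts <- table(cause = cause, stratum = strata)
  totals <- colSums(counts)
  out <- as.data.frame(counts, stringsAsFactors = FALSE)
  names(out) <- c("cause", "stratum", "n")
  out$pct <- pct_of(out$n, totals[as.character(out$stratum)])
  out <- out[order(out$stratum, match(out$cause, cause_levels())),
             c("stratum", "cause", "n", "pct")]
  rownames(out) <- NULL
  attr(out, "totals") <- totals
  class(out) <- c("cause_table", "data.frame")
  out
}

#' Cross-tabulate cause of stillbirth by maceration or maternal condition
#'
#' With `by` a vector (maceration status), columns are mutually exclusive
#' and jointly exhaustive and each column's percentages sum to 100 up to
#' rounding. With `by` a data.frame of condition flags, each stillbirth is
#' counted under every condition present, so columns are not mutually
#' exclusive and column totals may exceed the number of stillbirths.
#'
#' @param assignments output of [assign_cause()], or a vector of causes.
#' @param by maceration status vector (`macerated`, `non_macerated`,
#'   `unknown`) or a data.frame of tri-state condition flags, one column
#'   per reported condition.
#' @return data.frame of class `cause_table` in long form (`stratum` =
#'   column label); empty columns yield zero counts and 0 percentages.
#' @export
crosstab_cause <- function(assignments, by) {
  cause <- as_cause_factor(assignments)
  if (is.data.frame(by)) {
    stopifnot(nrow(by) == length(cause))
    pieces <- lapply(names(by), function(cond) {
      present <- flag_as_logical(by[[cond]])
      tab <- table(cause[present])
      data.frame(stratum = cond, cause = names(tab),
                 n = as.integer(tab),
                 pct = pct_of(as.integer(tab), sum(present)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pieces)
    totals <- vapply(by, function(x) sum(flag_as_logical(x)), integer(1))
    out$stratum <- factor(out$stratum, levels = names(by))
    out$cause <- factor(out$cause, levels = cause_levels())
    out <- out[order(out$stratum, match(out$cause, cause_levels())), ]
    rownames(out) <- NULL
    attr(out, "totals") <- totals
    class(out) <- c("cause_table", "data.frame")
    return(out)
  }
  by <- factor(by, levels = union(c("macerated", "non_macerated", "unknown"),
                                  unique(as.character(by))))
  tabulate_causes(cause, strata = by)
}

#' @export
print.cause_table <- function(x, ...) {
  wide <- stats::reshape(
    as.data.frame(x), direction = "wide", idvar = "cause",
    timevar = "stratum", v.names = c("n", "pct")
  )
  cat("Cause of stillbirth (N =",
      paste(names(attr(x, "totals")), attr(x, "totals"), sep = ":",
            collapse = ", "), ")\n")
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Write a cause table as CSV and JSON
#' @param tab a `cause_table`.
#' @param csv_path output CSV path.
#' @param json_path optional JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_cause_table <- function(tab, csv_path, json_path = NULL) {
  utils::write.csv(as.data.frame(tab), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(totals = as.list(attr(tab, "totals")),
           cells = as.data.frame(tab)),
      json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(csv_path)
}
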