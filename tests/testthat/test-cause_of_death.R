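# cause_of_death: hierarchy classifier, oracle equivalence, tabulations.

test_that("hierarchy levels fire in order with first-match-wins", {
  # dominance: all three of the first levels set -> trauma wins
  f <- make_flags(1, trauma = "true", major_anomaly = "true",
                  maternal_infection = "true")
  out <- assign_cause(f, ga_weeks = 25)
  expect_equal(as.character(out$cause), "trauma")
  expect_equal(out$rule_fired, 1L)

  # obstructed/prolonged labor alone -> asphyxia (rule 4)
  f <- make_flags(1, obstructed_prolonged_labor = "true")
  out <- assign_cause(f, ga_weeks = 36)
  expect_equal(as.character(out$cause), "asphyxia")
  expect_equal(out$rule_fired, 4L)

  # no conditions: GA drives prematurity vs unknown; missing GA -> unknown
  f <- make_flags(3)
  out <- assign_cause(f, ga_weeks = c(30, 33, NA))
  expect_equal(as.character(out$cause),
               c("prematurity", "unknown", "unknown"))
  expect_equal(out$rule_fired, c(5L, 6L, 6L))
})

test_that("unknown flags are treated as false but any true flag decides", {
  f <- make_flags(2, maternal_infection = c("unknown", "true"),
                  fetal_infection = c("unknown", "unknown"))
  out <- assign_cause(f, ga_weeks = c(40, 40))
  expect_equal(as.character(out$cause), c("unknown", "infection"))
})

test_that("asphyxia condition set is configurable", {
  f <- make_flags(1, breech_transverse = "true")
  # default: breech/transverse is not an asphyxia condition
  expect_equal(as.character(assign_cause(f, ga_weeks = 36)$cause),
               "unknown")
  withbr <- c(default_asphyxia_conditions(), "breech_transverse")
  expect_equal(as.character(
    assign_cause(f, ga_weeks = 36, asphyxia_conditions = withbr)$cause),
    "asphyxia")
  expect_error(assign_cause(f, asphyxia_conditions = "not_a_flag"),
               "unknown asphyxia")
})

test_that("classifier matches brute-force oracle over all flags x GA", {
  combos <- expand.grid(rep(list(c("false", "true")),
                            length(condition_flags())),
                        stringsAsFactors = FALSE)
  names(combos) <- condition_flags()
  gas <- c(NA, 20:40)
  grid <- combos[rep(seq_len(nrow(combos)), each = length(gas)), ]
  grid$ga_weeks <- rep(gas, nrow(combos))
  rownames(grid) <- NULL

  elapsed <- system.time(got <- assign_cause(grid))["elapsed"]
  expect_lt(elapsed, 1)

  want_cause <- character(nrow(grid))
  want_rule <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    o <- oracle_cause(grid[i, condition_flags()], grid$ga_weeks[i])
    want_cause[i] <- o$cause
    want_rule[i] <- o$rule
  }
  expect_identical(as.character(got$cause), want_cause)
  expect_identical(got$rule_fired, want_rule)
})

test_that("adding lower-priority flags never changes an assignment", {
  set.seed(42)
  rule_flags <- list(
    trauma = "trauma", congenital_anomaly = "major_anomaly",
    infection = c("maternal_infection", "fetal_infection"),
    asphyxia = default_asphyxia_conditions())
  for (rep in 1:200) {
    f <- make_flags(1)
    for (nm in condition_flags())
      f[[nm]] <- sample(c("true", "false"), 1)
    ga <- sample(c(NA, 20:40), 1)
    base <- assign_cause(f, ga_weeks = ga)
    # flip on one flag belonging to a strictly lower-priority rule
    lower <- base$rule_fired < 4
    candidates <- unlist(rule_flags[seq_along(rule_flags) >
                                      base$rule_fired])
    if (length(candidates) > 0) {
      f2 <- f
      f2[[sample(candidates, 1)]] <- "true"
      again <- assign_cause(f2, ga_weeks = ga)
      expect_identical(again$cause, base$cause)
      expect_identical(again$rule_fired, base$rule_fired)
    }
    # monotone in trauma: trauma forces cause regardless of the rest
    f$trauma <- "true"
    expect_equal(as.character(assign_cause(f, ga_weeks = ga)$cause),
                 "trauma")
  }
})

test_that("prematurity assignments always carry an observed GA below 32", {
  cfg <- lean_config(n_clusters = 5, births = 2000, rate = 0.05,
                     conditions = default_condition_probs())
  reg <- generate_registry(cfg, seed = 9)
  aset <- build_analysis_set(reg$records)
  sb <- aset$records[aset$records$outcome == "stillbirth", ]
  out <- assign_cause(sb)
  prem <- out$cause == "prematurity"
  expect_true(all(!is.na(sb$ga_weeks[prem]) & sb$ga_weeks[prem] < 32))
  # exactly one cause per stillbirth
  expect_equal(nrow(out), nrow(sb))
  expect_false(anyNA(out$cause))
})

test_that("cause tabulation reproduces report-style percentages", {
  # published total-column counts, N = 7188
  counts <- c(trauma = 1, congenital_anomaly = 531, infection = 1594,
              asphyxia = 3162, prematurity = 534, unknown = 1366)
  causes <- rep(names(counts), counts)
  tab <- tabulate_causes(causes)
  expect_equal(sum(tab$n), 7188)
  expect_equal(tab$pct[tab$cause == "asphyxia"], 44.0)
  expect_equal(tab$pct[tab$cause == "infection"], 22.2)
  expect_equal(tab$pct[tab$cause == "congenital_anomaly"], 7.4)
  expect_equal(tab$pct[tab$cause == "unknown"], 19.0)

  # a single assignment normalises to 100%
  one <- tabulate_causes("asphyxia")
  expect_equal(one$pct[one$cause == "asphyxia"], 100.0)
})

test_that("tabulation by stratum equals per-record classification", {
  cfg <- lean_config(n_clusters = 8, births = 1500, rate = 0.05,
                     conditions = default_condition_probs())
  reg <- generate_registry(cfg, seed = 21)
  aset <- build_analysis_set(reg$records)
  sb <- aset$records[aset$records$outcome == "stillbirth", ]
  tab <- tabulate_causes(assign_cause(sb), strata = sb$site)
  # one-by-one route
  slow <- table(vapply(seq_len(nrow(sb)), function(i)
    as.character(assign_cause(sb[i, ])$cause), ""))
  for (cz in names(slow))
    expect_equal(tab$n[tab$cause == cz], as.integer(slow[[cz]]))
  expect_equal(sum(tab$n), nrow(sb))
})

test_that("maceration cross-tab reproduces published column percentages", {
  mk <- function(counts) rep(names(counts), counts)
  nonmac <- c(trauma = 1, congenital_anomaly = 332, infection = 810,
              asphyxia = 2565, prematurity = 534, unknown = 698)  # N=4940
  mac <- c(trauma = 0, congenital_anomaly = 196, infection = 767,
           asphyxia = 582, prematurity = 0, unknown = 649)        # N=2194
  unk <- c(trauma = 0, congenital_anomaly = 3, infection = 17,
           asphyxia = 15, prematurity = 0, unknown = 19)          # N=54
  causes <- c(mk(nonmac), mk(mac), mk(unk))
  status <- c(rep("non_macerated", sum(nonmac)),
              rep("macerated", sum(mac)), rep("unknown", sum(unk)))
  xt <- crosstab_cause(causes, status)
  expect_equal(xt$pct[xt$stratum == "non_macerated" &
                        xt$cause == "asphyxia"], 51.9)
  expect_equal(xt$pct[xt$stratum == "macerated" &
                        xt$cause == "infection"], 35.0)
  # columns are exhaustive and percentages sum to 100 within rounding
  for (s in unique(xt$stratum)) {
    expect_equal(sum(xt$n[xt$stratum == s]),
                 as.integer(attr(xt, "totals")[as.character(s)]))
    expect_lt(abs(sum(xt$pct[xt$stratum == s]) - 100), 0.3)
  }
  # cross-tab marginals equal the overall tabulation
  overall <- tabulate_causes(causes)
  for (cz in cause_levels())
    expect_equal(sum(xt$n[xt$cause == cz]),
                 overall$n[overall$cause == cz])
})

test_that("maternal-condition cross-tab allows overlap and empty columns", {
  f <- make_flags(4,
                  hypertensive_disease = c("true", "true", "false",
                                           "false"),
                  antepartum_hemorrhage = c("true", "false", "false",
                                            "false"),
                  obstructed_prolonged_labor = "false")
  causes <- assign_cause(f, ga_weeks = c(36, 36, 30, NA))
  xt <- crosstab_cause(causes,
                       f[c("hypertensive_disease", "antepartum_hemorrhage",
                           "obstructed_prolonged_labor")])
  totals <- attr(xt, "totals")
  expect_equal(unname(totals["hypertensive_disease"]), 2L)
  expect_equal(unname(totals["antepartum_hemorrhage"]), 1L)
  # overlapping columns: totals sum above the number of stillbirths
  # that have at least one condition recorded (record 1 counts twice)
  n_any <- sum(Reduce(`|`, lapply(f[names(totals)], \(x) x == "true")))
  expect_gt(sum(totals), n_any)
  # empty column: zero counts, zero percentages, no division error
  empty <- xt[xt$stratum == "obstructed_prolonged_labor", ]
  expect_true(all(empty$n == 0))
  expect_true(all(empty$pct == 0))
})
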