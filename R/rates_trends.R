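# Stillbirth rates per 1000 births with confidence intervals, by site and
# year, including the continuing-cluster restriction for yearly trends.

#' Stillbirth rate per 1000 births
#'
#' Exact rate `1000 * n_stillbirths / n_births`. Display rounding (one
#' decimal) is left to report formatting; the returned value is exact.
#'
#' @param n_stillbirths stillbirth count.
#' @param n_births total births (live + still) in the denominator.
#' @param ci_method `"wilson"` (default, score interval on the binomial
#'   proportion) or `"cluster_robust"` (between-cluster variance; requires
#'   `clusters`).
#' @param clusters optional data.frame with per-cluster `n_stillbirths`,
#'   `n_births` for the cluster-robust interval.
#' @param stratum optional named list/vector of stratum labels (site, year,
#'   ...) copied onto the output row.
#' @param conf_level confidence level, default 0.95.
#' @return one-row data.frame of class `rate_estimate`: stratum labels,
#'   `n_stillbirths`, `n_births`, `rate_per_1000`, `ci_low`, `ci_high`,
#'   `ci_method`, `undefined` (TRUE when `n_births` is 0).
#' @examples
#' stillbirth_rate(15604, 552547)  # 28.2 per 1000
#' @export
stillbirth_rate <- function(n_stillbirths, n_births, ci_method = "wilson",
                            clusters = NULL, stratum = NULL,
                            conf_level = 0.95) {
  stopifnot_scalar_count(n_stillbirths, "n_stillbirths")
  stopifnot_scalar_count(n_births, "n_births")
  if (n_stillbirths > n_births)
    stop("n_stillbirths exceeds n_births", call. = FALSE)
  undefined <- n_births == 0
  if (undefined) {
    rate <- NA_real_
    ci <- c(NA_real_, NA_real_)
    method_used <- ci_method
  } else {
    rate <- 1000 * n_stillbirths / n_births
    ci_fit <- rate_ci(n_stillbirths, n_births, method = ci_method,
                      clusters = clusters, conf_level = conf_level)
    ci <- c(ci_fit$ci_low, ci_fit$ci_high)
    method_used <- ci_fit$method
  }
  out <- data.frame(n_stillbirths = as.integer(n_stillbirths),
                    n_births = as.integer(n_births),
                    rate_per_1000 = rate, ci_low = ci[1], ci_high = ci[2],
                    ci_method = method_used, undefined = undefined,
                    stringsAsFactors = FALSE)
  if (!is.null(stratum))
    out <- cbind(as.data.frame(as.list(stratum), stringsAsFactors = FALSE),
                 out)
  class(out) <- c("rate_estimate", "data.frame")
  out
}

#' Confidence interval for a stillbirth rate
#'
#' `wilson` computes the Wilson score interval for the binomial proportion
#' and scales it to per-1000. `cluster_robust` uses the ratio-estimator
#' between-cluster empirical variance of the cluster totals (normal
#' approximation): with cluster numerators \eqn{x_g}, denominators
#' \eqn{n_g}, overall rate \eqn{R = \sum x_g / \sum n_g},
#' \eqn{\widehat{var}(R) = \frac{G}{G-1} \sum_g (x_g - R n_g)^2 / (\sum_g
#' n_g)^2}. Identical cluster rates give a degenerate interval equal to
#' the point estimate. Fewer than 2 clusters falls back to Wilson with a
#' warning.
#'
#' @inheritParams stillbirth_rate
#' @param method `"wilson"` or `"cluster_robust"`.
#' @return list with `ci_low`, `ci_high` (per 1000) and `method` actually
#'   used.
#' @export
rate_ci <- function(n_stillbirths, n_births,
                    method = c("wilson", "cluster_robust"), clusters = NULL,
                    conf_level = 0.95) {
  method <- match.arg(method)
  if (n_births <= 0) return(list(ci_low = NA_real_, ci_high = NA_real_,
                                 method = method))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (method == "cluster_robust") {
    ok <- is.data.frame(clusters) && nrow(clusters) >= 2 &&
      all(c("n_stillbirths", "n_births") %in% names(clusters))
    if (!ok) {
      warning("cluster_robust CI requires >= 2 clusters; ",
              "falling back to wilson", call. = FALSE)
      method <- "wilson"
    } else {
      g <- nrow(clusters)
      r <- n_stillbirths / n_births
      resid <- clusters$n_stillbirths - r * clusters$n_births
      v <- g / (g - 1) * sum(resid^2) / n_births^2
      half <- z * sqrt(v)
      return(list(ci_low = 1000 * max(0, r - half),
                  ci_high = 1000 * min(1, r + half),
                  method = "cluster_robust"))
    }
  }
  p <- n_stillbirths / n_births
  denom <- 1 + z^2 / n_births
  center <- (p + z^2 / (2 * n_births)) / denom
  half <- z * sqrt(p * (1 - p) / n_births + z^2 / (4 * n_births^2)) / denom
  list(ci_low = 1000 * max(0, center - half),
       ci_high = 1000 * min(1, center + half),
       method = "wilson")
}

outcome_column <- function(records) {
  if (inherits(records, "analysis_set")) records <- records$records
  if (!("outcome" %in% names(records)))
    stop("records need an `outcome` column (run build_analysis_set first)",
         call. = FALSE)
  records
}

#' Select clusters active throughout the study period
#'
#' The yearly trend analysis is restricted to "continuing" clusters: those
#' contributing at least `min_births_per_year` included births in every
#' calendar year of the span (sites changed their cluster sets over time).
#'
#' @param records analysis-set records (or an `analysis_set`).
#' @param start_year,end_year span of calendar years, default 2010--2018.
#' @param min_births_per_year minimum included births a cluster must have
#'   in each year to count as continuing (default 1).
#' @return data.frame of `site`, `cluster_id` for the retained clusters
#'   (cluster ids are unique within site only).
#' @export
select_continuing_clusters <- function(records, start_year = 2010,
                                       end_year = 2018,
                                       min_births_per_year = 1) {
  records <- outcome_column(records)
  years <- seq.int(start_year, end_year)
  if (nrow(records) == 0)
    return(data.frame(site = character(0), cluster_id = character(0),
                      stringsAsFactors = FALSE))
  records <- records[records$year %in% years, , drop = FALSE]
  key <- interaction(records$site, records$cluster_id, drop = TRUE,
                     sep = "\r")
  tab <- table(key, factor(records$year, levels = years))
  keep <- rownames(tab)[apply(tab >= min_births_per_year, 1, all)]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(site = vapply(parts, `[`, "", 1),
                    cluster_id = vapply(parts, `[`, "", 2),
                    stringsAsFactors = FALSE)
  out[order(out$site, out$cluster_id), , drop = FALSE]
}

#' Stillbirth rates by site and year
#'
#' One [stillbirth_rate()] row per (site, year). Site-years with zero
#' births are reported with the `undefined` flag, never dropped silently.
#'
#' @param records analysis-set records (or an `analysis_set`).
#' @param continuing_only restrict to [select_continuing_clusters()]
#'   clusters (trend analysis) — default `FALSE`.
#' @param ci_method passed to [stillbirth_rate()]; for
#'   `"cluster_robust"`, per-cluster counts within each site-year are used.
#' @param start_year,end_year span; default the data range.
#' @return `rate_estimate` data.frame with `site` and `year` columns.
#' @export
yearly_rate_series <- function(records, continuing_only = FALSE,
                               ci_method = "wilson", start_year = NULL,
                               end_year = NULL) {
  records <- outcome_column(records)
  if (nrow(records) == 0)
    return(structure(data.frame(), class = c("rate_estimate",
                                             "data.frame")))
  start_year <- start_year %||% min(records$year)
  end_year <- end_year %||% max(records$year)
  if (continuing_only) {
    keep <- select_continuing_clusters(records, start_year, end_year)
    key <- paste(records$site, records$cluster_id, sep = "\r")
    records <- records[key %in% paste(keep$site, keep$cluster_id,
                                      sep = "\r"), , drop = FALSE]
  }
  years <- seq.int(start_year, end_year)
  sites <- sort(unique(records$site))
  rows <- list()
  for (s in sites) {
    site_rec <- records[records$site == s, , drop = FALSE]
    for (y in years) {
      rec <- site_rec[site_rec$year == y, , drop = FALSE]
      cl <- NULL
      if (ci_method == "cluster_robust" && nrow(rec) > 0) {
        sb_by <- tapply(rec$outcome == "stillbirth", rec$cluster_id, sum)
        n_by <- tapply(rec$outcome, rec$cluster_id, length)
        cl <- data.frame(n_stillbirths = as.integer(sb_by),
                         n_births = as.integer(n_by))
      }
      rows[[paste(s, y)]] <- stillbirth_rate(
        sum(rec$outcome == "stillbirth"), nrow(rec), ci_method = ci_method,
        clusters = cl, stratum = list(site = s, year = y))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rate_estimate", "data.frame")
  out
}

#' Site-level rate table with maceration distribution
#'
#' Reproduces the style of a site-summary table: per-site (plus regional
#' aggregates and overall) births, stillbirths, rate per 1000 with CI, and
#' the percentage distribution of maceration status among stillbirths.
#'
#' @param records analysis-set records (or an `analysis_set`).
#' @param ci_method passed to [stillbirth_rate()].
#' @return `rate_estimate` data.frame with a `stratum` column and
#'   maceration percentage columns.
#' @export
site_rate_table <- function(records, ci_method = "wilson") {
  records <- outcome_column(records)
  groups <- c(list(total = registry_sites(),
                   african_sites = african_sites(),
                   asian_sites = asian_sites()),
              stats::setNames(as.list(sort(unique(records$site))),
                              sort(unique(records$site))))
  rows <- lapply(names(groups), function(g) {
    rec <- records[records$site %in% groups[[g]], , drop = FALSE]
    cl <- NULL
    if (ci_method == "cluster_robust" && nrow(rec) > 0) {
      k <- paste(rec$site, rec$cluster_id, sep = "\r")
      cl <- data.frame(
        n_stillbirths = as.integer(tapply(rec$outcome == "stillbirth", k,
                                          sum)),
        n_births = as.integer(tapply(rec$outcome, k, length)))
    }
    est <- stillbirth_rate(sum(rec$outcome == "stillbirth"), nrow(rec),
                           ci_method = ci_method, clusters = cl,
                           stratum = list(stratum = g))
    sb <- rec[rec$outcome == "stillbirth", , drop = FALSE]
    est$macerated_pct <- pct_of(sum(sb$maceration == "macerated",
                                    na.rm = TRUE), nrow(sb))
    est$non_macerated_pct <- pct_of(sum(sb$maceration == "non_macerated",
                                        na.rm = TRUE), nrow(sb))
    est$maceration_unknown_pct <- pct_of(
      sum(is.na(sb$maceration) | sb$maceration == "unknown"), nrow(sb))
    est
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rate_estimate", "data.frame")
  out
}

#' @export
print.rate_estimate <- function(x, digits = 1, ...) {
  y <- as.data.frame(x)
  for (col in c("rate_per_1000", "ci_low", "ci_high"))
    if (col %in% names(y)) y[[col]] <- round_half_up(y[[col]], digits)
  print(y, row.names = FALSE)
  invisible(x)
}
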