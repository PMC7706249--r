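# Relative risks of stillbirth under a log-link binomial model with
# cluster-correlated variance.
#
# Point estimation follows the marginal (GEE) formulation: a log-link
# binomial mean model fitted by Fisher scoring, with either an independence
# or an exchangeable working correlation, and standard errors from the
# cluster-level sandwich estimator. No GEE library is available in the
# supported environment, so the estimating equations are solved here
# directly; the exchangeable working correlation is inverted in closed form
# (R^{-1} = (I - c J)/(1 - alpha), c = alpha / (1 + (n_g - 1) alpha)), so
# each iteration is linear in the number of observations. If the
# log-binomial fit fails to converge (fitted risks pushed to 1), the
# documented fallback is a log-link Poisson model with the same sandwich
# variance — standard practice for risk-ratio estimation.

#' Crude relative risk from a 2x2 table
#'
#' `rr = (a/(a+b)) / (c/(c+d))` with a log-scale Wald interval using
#' `se = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`.
#'
#' @param a exposed cases (stillbirths), `b` exposed non-cases, `c`
#'   reference cases, `d` reference non-cases. Alternatively pass a 2x2
#'   matrix as `a` (rows = exposed/reference, cols = case/non-case).
#' @param b,c,d cell counts, see `a`.
#' @param conf_level confidence level (default 0.95).
#' @param continuity add 0.5 to every cell when a zero case cell makes the
#'   estimate degenerate (default `FALSE`: the estimate is returned flagged
#'   with `degenerate = TRUE` instead).
#' @param exposure,reference labels copied to the output.
#' @return one-row data.frame of class `risk_estimate`.
#' @examples
#' crude_rr(7777, 276529, 6260, 260354)  # about 1.17
#' @export
crude_rr <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95,
                     continuity = FALSE, exposure = "exposed",
                     reference = "reference") {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("all four cells must be non-negative counts", call. = FALSE)
  if ((a + b) == 0 || (c + d) == 0)
    stop("both row totals must be positive", call. = FALSE)
  degenerate <- (a == 0 || c == 0)
  if (degenerate && continuity) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  rr <- (a / (a + b)) / (c / (c + d))
  if (a > 0 && c > 0) {
    se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(log(rr) + c(-1, 1) * z * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  out <- data.frame(
    exposure = exposure, reference = reference,
    rr = rr, ci_low = ci[1], ci_high = ci[2],
    n_exposed_cases = cells["a"], n_exposed = cells["a"] + cells["b"],
    n_ref_cases = cells["c"], n_ref = cells["c"] + cells["d"],
    model = "crude", cluster_unit = NA_character_,
    working_correlation = NA_character_,
    degenerate = degenerate && !continuity,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("risk_estimate", "data.frame")
  out
}

# Solve the GEE for a log-link mean model.
#   y: 0/1 outcome; X: model matrix; cluster: factor; corstr:
#   "independence" or "exchangeable"; variance: "binomial" (mu(1-mu)) or
#   "poisson" (mu, the fallback).
# Returns beta, cluster-sandwich vcov, alpha, convergence flag.
gee_log_fit <- function(y, X, cluster, corstr = "independence",
                        variance = "binomial", maxit = 60, tol = 1e-10) {
  n <- length(y)
  p <- ncol(X)
  cluster <- droplevels(as.factor(cluster))
  binom <- variance == "binomial"

  # start from the log of the pooled rate; slopes at zero are always an
  # interior point for the log-binomial constraint eta < 0
  beta <- c(log(max(mean(y), 1 / (2 * n))), rep(0, p - 1))
  alpha <- 0
  converged <- FALSE

  cluster_quants <- function(mu, e) {
    # per-cluster building blocks for the closed-form exchangeable inverse
    Z <- X * (if (binom) mu / sqrt(mu * (1 - mu)) else sqrt(mu))
    zs <- rowsum(Z, cluster)                       # G x p colsums
    es <- rowsum(e, cluster)[, 1]                  # G    sums
    ng <- as.vector(table(cluster))
    list(Z = Z, zs = zs, es = es, ng = ng)
  }

  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    v <- if (binom) mu * (1 - mu) else mu
    e <- (y - mu) / sqrt(v)

    if (corstr == "exchangeable") {
      ng <- as.vector(table(cluster))
      npairs <- sum(ng * (ng - 1)) / 2
      if (npairs > p) {
        phi <- sum(e^2) / (n - p)
        es_ <- rowsum(e, cluster)[, 1]
        e2_ <- rowsum(e^2, cluster)[, 1]
        alpha <- sum((es_^2 - e2_) / 2) / phi / (npairs - p)
        alpha <- min(max(alpha, 0), 0.95)
      } else alpha <- 0
    }

    q <- cluster_quants(mu, e)
    c1 <- 1 / (1 - alpha)
    c2 <- alpha / (1 + (q$ng - 1) * alpha)
    U <- c1 * (crossprod(q$Z, e) - crossprod(q$zs, c2 * q$es))
    H <- c1 * (crossprod(q$Z) - crossprod(q$zs, q$zs * c2))

    step <- tryCatch(solve(H, U), error = function(e) NULL)
    if (is.null(step)) break
    # step-halve to keep all fitted risks below 1 under the binomial model
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * drop(step)
      eta_new <- drop(X %*% beta_new)
      if (!binom || max(eta_new) < -1e-8) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    if (binom && max(drop(X %*% (beta + lambda * drop(step)))) >= -1e-8)
      break  # boundary: declare non-convergence, caller falls back
    delta <- lambda * drop(step)
    beta <- beta + delta
    if (max(abs(delta)) < 1e-9 || max(abs(U)) < tol) {
      converged <- TRUE
      break
    }
  }

  # cluster sandwich: B^{-1} M B^{-1} with per-cluster score contributions
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  v <- if (binom) mu * (1 - mu) else mu
  e <- (y - mu) / sqrt(v)
  q <- cluster_quants(mu, e)
  c1 <- 1 / (1 - alpha)
  c2 <- alpha / (1 + (q$ng - 1) * alpha)
  H <- c1 * (crossprod(q$Z) - crossprod(q$zs, q$zs * c2))
  ug <- c1 * (rowsum(q$Z * e, cluster) - (c2 * q$es) * q$zs)
  Hinv <- tryCatch(solve(H), error = function(e) NULL)
  vcov <- if (is.null(Hinv)) matrix(NA_real_, p, p)
          else Hinv %*% crossprod(ug) %*% Hinv
  list(beta = beta, vcov = vcov, alpha = alpha, converged = converged,
       n_clusters = nlevels(cluster))
}

#' Cluster-correlated relative risk for one exposure
#'
#' Fits a univariable log-link binomial marginal model of stillbirth on a
#' categorical exposure, with variance from the cluster-level sandwich
#' estimator (generalized estimating equations). With an independence
#' working correlation the point estimate equals the crude relative risk
#' computed from the pooled counts; the exchangeable option re-weights
#' clusters. Exposure levels with zero cases in either arm (separation
#' under the log link) are flagged and returned without an estimate.
#'
#' @param records analysis-set records: needs `outcome`, `site`,
#'   `cluster_id` and the exposure column (join [derive_covariates()]
#'   output first for derived exposures).
#' @param exposure name of the exposure column.
#' @param reference_level reference category; defaults to the first level
#'   (logical exposures default to `FALSE`).
#' @param cluster_unit `"cluster"` (geographic cluster within site, the
#'   default) or `"site"`.
#' @param working_correlation `"independence"` (default) or
#'   `"exchangeable"`.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame of class `risk_estimate`, one row per non-reference
#'   exposure level, with counts, `rr`, CI bounds, model metadata, the
#'   estimated working correlation `alpha`, and `fallback = TRUE` when the
#'   log-binomial fit did not converge and the Poisson fallback was used.
#' @export
cluster_rr <- function(records, exposure, reference_level = NULL,
                       cluster_unit = c("cluster", "site"),
                       working_correlation = c("independence",
                                               "exchangeable"),
                       conf_level = 0.95) {
  cluster_unit <- match.arg(cluster_unit)
  working_correlation <- match.arg(working_correlation)
  records <- outcome_column(records)
  if (!exposure %in% names(records))
    stop("exposure column `", exposure, "` not found", call. = FALSE)

  x <- records[[exposure]]
  keep <- !is.na(x) & !is.na(records$outcome)
  rec <- records[keep, , drop = FALSE]
  x <- x[keep]
  if (is.logical(x)) x <- ifelse(x, "true", "false")
  x <- as.character(x)
  levels_present <- unique(x)
  if (length(levels_present) < 2)
    stop("exposure `", exposure, "` is constant after dropping missing",
         call. = FALSE)
  if (is.null(reference_level))
    reference_level <- if ("false" %in% levels_present) "false"
                       else sort(levels_present)[1]
  if (!reference_level %in% levels_present)
    stop("reference level `", reference_level, "` absent from data",
         call. = FALSE)
  lev <- c(reference_level, sort(setdiff(levels_present, reference_level)))
  xf <- factor(x, levels = lev)
  y <- as.integer(rec$outcome == "stillbirth")
  cl <- if (cluster_unit == "cluster") {
    paste(rec$site, rec$cluster_id, sep = "\r")
  } else rec$site
  if (length(unique(cl)) < 2)
    stop("cluster-robust variance needs >= 2 clusters", call. = FALSE)

  counts <- data.frame(
    level = lev,
    cases = as.integer(tapply(y, xf, sum)),
    n = as.integer(table(xf)),
    stringsAsFactors = FALSE
  )
  ref_cases <- counts$cases[1]
  ref_n <- counts$n[1]
  # separation: a level (or the reference) with zero cases has no finite
  # log-RR; such levels are flagged and excluded from the fit
  sep_levels <- counts$level[counts$cases == 0]
  ref_separated <- reference_level %in% sep_levels
  fit_levels <- setdiff(lev, setdiff(sep_levels, reference_level))

  beta <- vcov <- NULL
  alpha <- NA_real_
  fallback <- FALSE
  if (!ref_separated && length(fit_levels) >= 2) {
    sub <- xf %in% fit_levels
    xs <- factor(as.character(xf[sub]), levels = fit_levels)
    X <- stats::model.matrix(~xs)
    fit <- gee_log_fit(y[sub], X, cl[sub], corstr = working_correlation,
                       variance = "binomial")
    if (!fit$converged) {
      fit <- gee_log_fit(y[sub], X, cl[sub], corstr = working_correlation,
                         variance = "poisson")
      fallback <- TRUE
    }
    if (fit$converged) {
      beta <- fit$beta
      vcov <- fit$vcov
      alpha <- fit$alpha
    }
  }

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(setdiff(lev, reference_level), function(levl) {
    i <- match(levl, counts$level)
    est <- c(NA_real_, NA_real_, NA_real_)
    if (!is.null(beta) && levl %in% fit_levels) {
      j <- match(levl, fit_levels)  # coefficient index (j-th column)
      se <- sqrt(vcov[j, j])
      est <- c(exp(beta[j]), exp(beta[j] - z * se), exp(beta[j] + z * se))
    }
    data.frame(
      exposure = paste0(exposure, ":", levl), reference = reference_level,
      rr = est[1], ci_low = est[2], ci_high = est[3],
      n_exposed_cases = counts$cases[i], n_exposed = counts$n[i],
      n_ref_cases = ref_cases, n_ref = ref_n,
      model = "cluster_gee", cluster_unit = cluster_unit,
      working_correlation = working_correlation,
      degenerate = levl %in% sep_levels || ref_separated,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$alpha <- alpha
  out$fallback <- fallback
  rownames(out) <- NULL
  class(out) <- c("risk_estimate", "data.frame")
  out
}

#' Relative risks for a set of exposures
#'
#' Convenience wrapper running [cluster_rr()] over several exposure
#' columns and stacking the results.
#'
#' @param records analysis-set records joined with covariates.
#' @param exposures character vector of exposure column names.
#' @param references optional named list of reference levels per exposure.
#' @param ... passed to [cluster_rr()].
#' @return stacked `risk_estimate` data.frame.
#' @export
risk_table <- function(records, exposures, references = list(), ...) {
  rows <- lapply(exposures, function(ex) {
    tryCatch(
      cluster_rr(records, ex, reference_level = references[[ex]], ...),
      error = function(e) {
        warning("exposure `", ex, "` skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  out
}

#' @export
print.risk_estimate <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  for (col in c("rr", "ci_low", "ci_high"))
    y[[col]] <- round(y[[col]], digits)
  print(y, row.names = FALSE)
  invisible(x)
}
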