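# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; report tables in this field round
#' half up (2.25 -> 2.3). Used for all displayed rates and percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  # tiny epsilon guards against binary representation of exact halves
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# percentage of a count over a total, safe at total = 0
pct_of <- function(n, total, digits = 1) {
  ifelse(total > 0, round_half_up(100 * n / total, digits), 0)
}

# tri-state flag ("true"/"false"/"unknown", logical, or NA) -> logical,
# with unknown/NA mapped to FALSE (the classifier's convention)
flag_as_logical <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(as.character(x))
  !is.na(x) & x %in% c("true", "t", "yes", "1")
}

stopifnot_scalar_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || !is.numeric(x) || x < 0 || x != floor(x))
    stop(sprintf("`%s` must be a single non-negative integer", name),
         call. = FALSE)
  invisible(x)
}
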