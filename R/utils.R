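#' Round half away from zero
#'
#' Commercial rounding used for report output: 0.005 rounds to 0.01 and
#' -0.005 to -0.01, unlike [base::round()]'s banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stop() wrapper: all package errors go through this so messages carry a
# consistent "cuffbp: " prefix and no call
bp_abort <- function(...) {
  stop("cuffbp: ", ..., call. = FALSE)
}

bp_warn <- function(...) {
  warning("cuffbp: ", ..., call. = FALSE)
}

# scalar finite numeric check
is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_number <- function(x, name, positive = FALSE) {
  if (!is_number(x)) bp_abort(name, " must be a single finite number")
  if (positive && x <= 0) bp_abort(name, " must be > 0")
  invisible(x)
}

check_range <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] > x[2]) {
    bp_abort(name, " must be a finite non-empty range c(lo, hi)")
  }
  if (positive && x[1] <= 0) bp_abort(name, " must be positive")
  invisible(x)
}

# moving-average smoother with edge replication; w forced odd
moving_average <- function(x, w) {
  w <- max(3L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  n <- length(x)
  xp <- c(rep(x[1], h), x, rep(x[n], h))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(h + 1L):(h + n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
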