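#' @importFrom stats chisq.test optimize rbeta rbinom rpois runif setNames
#'   pchisq qbeta cor approx isoreg median quantile
#' @importFrom utils head tail write.table read.table
NULL

.datatable.aware <- TRUE

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's .Random.seed is restored afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Haldane map function
#'
#' Convert a recombination fraction to a map distance in centimorgan under
#' the no-interference (Haldane) model, d = -50 ln(1 - 2r), and back.
#'
#' @param r Recombination fraction(s) in `[0, 0.5]`.
#' @param d Map distance(s) in centimorgan, `>= 0`.
#' @param max_cM Distances are capped at this value so that `r` arbitrarily
#'   close to 0.5 stays finite. Default 250 cM.
#' @return `haldane_cM()` returns distances in cM; `haldane_r()` returns
#'   recombination fractions.
#' @examples
#' haldane_cM(0.1) # 11.157...
#' haldane_r(haldane_cM(0.25))
#' @export
haldane_cM <- function(r, max_cM = 250) {
  stopifnot(all(r >= 0 & r <= 0.5))
  pmin(-50 * log1p(-2 * r), max_cM)
}

#' @rdname haldane_cM
#' @export
haldane_r <- function(d) {
  stopifnot(all(d >= 0))
  (1 - exp(-d / 50)) / 2
}

#' Round half away from zero
#'
#' Base R rounds half to even; assembly/BUSCO percentage tables
#' conventionally round half away from zero (97.15 -> 97.2). Used by all
#' percentage reports in this package.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}
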