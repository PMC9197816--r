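#' @keywords internal
"_PACKAGE"

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded draws inside the package never disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic operation in the package draws from a stream identified by
#' a short string key, so any sub-draw of a larger simulation can be
#' regenerated on its own. The mapping is a fixed integer hash of
#' (seed, key), kept strictly below 2^31.
#'
#' @param seed master integer seed.
#' @param key character tag naming the sub-stream.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(1, "control")
#' derive_seed(1, "stroke")
derive_seed <- function(seed, key) {
  stopifnot(is.character(key), length(key) == 1L)
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(key)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

#' Draw from a truncated normal distribution by inversion
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the parent normal.
#' @param lower,upper truncation bounds.
#' @return numeric vector of length `n` inside (lower, upper).
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("`sd` must be non-negative", call. = FALSE)
  if (sd == 0) {
    if (mean <= lower || mean >= upper) {
      stop("degenerate truncation: point mass outside (lower, upper)", call. = FALSE)
    }
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < 1e-12) {
    stop(sprintf(
      "impossible truncation window [%g, %g] for N(%g, %g)",
      lower, upper, mean, sd
    ), call. = FALSE)
  }
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Draw from a symmetric Beta(kappa, kappa) truncated to (lower, upper)
#'
#' @param n number of draws.
#' @param kappa concentration parameter (> 0).
#' @param lower,upper truncation bounds in (0, 1).
#' @return numeric vector in (lower, upper).
#' @keywords internal
rtruncbeta_sym <- function(n, kappa, lower = 0.15, upper = 0.85) {
  if (kappa <= 0) stop("`kappa` must be > 0", call. = FALSE)
  plo <- stats::pbeta(lower, kappa, kappa)
  phi <- stats::pbeta(upper, kappa, kappa)
  stats::qbeta(plo + stats::runif(n) * (phi - plo), kappa, kappa)
}

# shared argument checker: a single logical (or 0/1) vector with no NAs
check_binary <- function(x, name) {
  if (is.logical(x)) x <- as.integer(x)
  if (!is.numeric(x) || anyNA(x) || !all(x %in% c(0, 1))) {
    stop(sprintf("`%s` must be logical or 0/1 with no missing values", name),
         call. = FALSE)
  }
  x
}
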