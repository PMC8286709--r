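#' Looking-time distribution families
#'
#' Five two-parameter probability families for positive looking times (LTs),
#' addressed everywhere by one-letter codes:
#' \describe{
#'   \item{N}{truncated normal: `y ~ Normal(z, sigma)` restricted to `y > 0`;
#'     additive model, `z` in seconds.}
#'   \item{E}{truncated normal with exponential mean: `y ~ Normal(exp(z), sigma)`
#'     restricted to `y > 0`; multiplicative habituation state, additive
#'     normal residual on the seconds scale.}
#'   \item{L}{lognormal: `log y ~ Normal(z, sigma)`.}
#'   \item{W}{Weibull with shape `sigma` and scale `exp(z)`.}
#'   \item{G}{gamma with shape `sigma` and scale `exp(z)`.}
#' }
#' All families map a real habituation state `z` and a positive nuisance
#' parameter `sigma` to a distribution supported on the positive reals.
#'
#' @return `lt_families()` returns the five family codes.
#' @export
lt_families <- function() c("N", "E", "L", "W", "G")

# internal: validate and normalize a family code
match_family <- function(family) {
  if (length(family) != 1L || !is.character(family))
    stop("`family` must be a single character code", call. = FALSE)
  fam <- toupper(family)
  if (fam == "X") fam <- "E" # alias used in some report tables
  if (!fam %in% lt_families())
    stop("unknown family code: ", family, call. = FALSE)
  fam
}

family_index <- function(family) {
  match(match_family(family), lt_families()) - 1L
}

check_pos <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("`", name, "` must be positive and finite", call. = FALSE)
  invisible(x)
}

#' Log-density of a looking-time family
#'
#' Evaluates `log f(y; z, sigma)` for one of the five families. The truncated
#' normal families (N, E) include the truncation normalizer
#' `Phi(mean/sigma)` so that every density integrates to one on
#' `(0, Inf)` and log-likelihoods are comparable across families.
#'
#' @param family one of `"N"`, `"E"`, `"L"`, `"W"`, `"G"`.
#' @param y positive looking time(s) in seconds.
#' @param z real habituation state.
#' @param sigma positive nuisance parameter.
#' @return log-density, recycled to the common length of `y`, `z`, `sigma`.
#' @examples
#' lt_logpdf("G", 1, 0, 1) # gamma with shape 1 is the unit-rate exponential
#' @export
lt_logpdf <- function(family, y, z, sigma) {
  fam <- match_family(family)
  check_pos(y, "y")
  check_pos(sigma, "sigma")
  if (any(!is.finite(z))) stop("`z` must be finite", call. = FALSE)
  switch(fam,
    N = stats::dnorm(y, z, sigma, log = TRUE) -
      stats::pnorm(z / sigma, log.p = TRUE),
    E = stats::dnorm(y, exp(z), sigma, log = TRUE) -
      stats::pnorm(exp(z) / sigma, log.p = TRUE),
    L = stats::dlnorm(y, z, sigma, log = TRUE),
    W = stats::dweibull(y, shape = sigma, scale = exp(z), log = TRUE),
    G = stats::dgamma(y, shape = sigma, scale = exp(z), log = TRUE)
  )
}

# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# internal vectorized sampler using the current RNG stream
family_sample <- function(fam, n, z, sigma) {
  switch(fam,
    N = {
      # inverse-CDF draw from Normal(z, sigma) truncated to (0, Inf)
      u <- stats::runif(n)
      z + sigma * stats::qnorm(stats::pnorm(z / sigma) * (1 - u),
                               lower.tail = FALSE)
    },
    E = {
      m <- exp(z)
      u <- stats::runif(n)
      m + sigma * stats::qnorm(stats::pnorm(m / sigma) * (1 - u),
                               lower.tail = FALSE)
    },
    L = stats::rlnorm(n, z, sigma),
    W = stats::rweibull(n, shape = sigma, scale = exp(z)),
    G = stats::rgamma(n, shape = sigma, scale = exp(z))
  )
}

#' Draw looking times from a family
#'
#' @inheritParams lt_logpdf
#' @param n number of draws.
#' @param seed optional integer; when given, draws are reproducible and the
#'   caller's RNG state is left untouched.
#' @return `n` positive looking times.
#' @export
lt_sample <- function(family, z, sigma, n, seed = NULL) {
  fam <- match_family(family)
  check_pos(sigma, "sigma")
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  if (any(!is.finite(z))) stop("`z` must be finite", call. = FALSE)
  if (is.null(seed)) family_sample(fam, n, z, sigma)
  else with_seed(seed, family_sample(fam, n, z, sigma))
}

#' Expected log looking time (log geometric mean)
#'
#' For the three log-link families the geometric mean of the distribution is
#' a linear function of `z`: `E[log Y]` equals `z` for the lognormal,
#' `z - gamma_Euler / sigma` for the Weibull and `z + digamma(sigma)` for the
#' gamma family. The truncated normal families have no geometric-mean
#' interpretation of `z` and are rejected.
#'
#' @inheritParams lt_logpdf
#' @return `E[log Y]`.
#' @export
lt_log_geometric_mean <- function(family, z, sigma) {
  fam <- match_family(family)
  check_pos(sigma, "sigma")
  switch(fam,
    L = z + 0 * sigma,
    W = z - euler_gamma / sigma,
    G = z + digamma(sigma),
    stop("log geometric mean is linear in z only for families L, W, G",
         call. = FALSE)
  )
}

euler_gamma <- -digamma(1)

#' Expected Fisher information of a family
#'
#' Expected information for a single observation in the `(z, sigma)`
#' parametrization. For the truncated normal families (N, E) the information
#' of the untruncated normal is returned (the truncation correction is
#' negligible when `mean/sigma > 3`), matching the standard textbook results
#' for the normal family.
#'
#' Closed forms: for L (and N, where `z` is the mean),
#' `diag(1, 2) / sigma^2`; for E the `z` entry picks up the factor
#' `exp(2 z)` from the chain rule; for W,
#' `I_zz = sigma^2`, `I_z,sigma = -(1 - gamma_Euler)`,
#' `I_sigma,sigma = (pi^2/6 + (1 - gamma_Euler)^2) / sigma^2`; for G,
#' `I_zz = sigma`, `I_z,sigma = 1`, `I_sigma,sigma = trigamma(sigma)`.
#'
#' @inheritParams lt_logpdf
#' @return symmetric positive-definite 2x2 matrix with dimnames
#'   `c("z", "sigma")`.
#' @export
lt_fisher_information <- function(family, z = 0, sigma) {
  fam <- match_family(family)
  check_pos(sigma, "sigma")
  info <- switch(fam,
    N = diag(c(1, 2)) / sigma^2,
    E = diag(c(exp(2 * z), 2)) / sigma^2,
    L = diag(c(1, 2)) / sigma^2,
    W = {
      g1 <- 1 - euler_gamma
      matrix(c(sigma^2, -g1, -g1, (pi^2 / 6 + g1^2) / sigma^2), 2, 2)
    },
    G = matrix(c(sigma, 1, 1, trigamma(sigma)), 2, 2)
  )
  dimnames(info) <- list(c("z", "sigma"), c("z", "sigma"))
  if (!all(is.finite(info)) || det(info) <= 0 || info[1, 1] <= 0)
    stop("Fisher information is not positive definite", call. = FALSE)
  info
}

#' Asymptotic correlation between the two parameter estimates
#'
#' Magnitude of the correlation between the maximum-likelihood estimates of
#' `z` and `sigma` implied by the inverse Fisher information. The normal-type
#' and lognormal families are parameter-orthogonal (correlation 0). The
#' Weibull correlation, `(1 - g) / sqrt(pi^2/6 + (1 - g)^2)` with `g` Euler's
#' constant, is about 0.31 and does not depend on `sigma`. The gamma
#' correlation is `1 / sqrt(sigma * trigamma(sigma))`: it increases with
#' `sigma`, approaching 0 as `sigma -> 0` and 1 as `sigma -> Inf`.
#'
#' The magnitude is returned; the signed correlation of the estimates is the
#' sign of the off-diagonal of the inverse information, `-sign(I[z, sigma])`:
#' positive for W and negative for G (the gamma shape and scale trade off
#' against the well-determined mean `sigma * exp(z)`).
#'
#' @inheritParams lt_logpdf
#' @return correlation magnitude in `[0, 1)`.
#' @export
lt_parameter_correlation <- function(family, sigma) {
  fam <- match_family(family)
  check_pos(sigma, "sigma")
  switch(fam,
    N = 0 * sigma,
    E = 0 * sigma,
    L = 0 * sigma,
    W = {
      g1 <- 1 - euler_gamma
      rep(g1 / sqrt(pi^2 / 6 + g1^2), length(sigma))
    },
    G = 1 / sqrt(sigma * trigamma(sigma))
  )
}

#' Percent transform of a log-scale change
#'
#' Converts a change on the habituation-state (log) scale into a
#' multiplicative percent change in looking time: `100 * (exp(base + z) - 1)`.
#' The default base of 0 gives the percent change relative to no change.
#' `percent_change_inverse()` is the exact inverse (at the same base).
#'
#' @param z_delta change on the log scale (finite real).
#' @param base base level on the log scale (default 0).
#' @return percent change.
#' @examples
#' percent_change(log(2))   # 100: a doubling
#' percent_change(log(0.93)) # -7: a 7 percent decrease per trial
#' @export
percent_change <- function(z_delta, base = 0) {
  if (any(!is.finite(z_delta)) || any(!is.finite(base)))
    stop("`z_delta` and `base` must be finite", call. = FALSE)
  100 * (exp(base + z_delta) - 1)
}

#' @rdname percent_change
#' @param percent percent change, greater than -100.
#' @export
percent_change_inverse <- function(percent, base = 0) {
  if (any(!is.finite(percent)) || any(percent <= -100))
    stop("`percent` must be finite and greater than -100", call. = FALSE)
  log(1 + percent / 100) - base
}
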