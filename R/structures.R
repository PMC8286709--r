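#' Time structures of the habituation state
#'
#' Three structures map an infant's parameters and a trial index to the
#' habituation state `z` that drives the looking-time distribution:
#' \describe{
#'   \item{T (trend)}{`z_t = alpha + beta * t + gamma * [t > d]` -- the
#'     dishabituation term switches on strictly after the last habituation
#'     trial `d` and stays on for every test trial.}
#'   \item{Q (quadratic)}{`z_t = alpha + beta * (t - delta)^2 + gamma *
#'     [t > d]` with a peak (for `beta < 0`) at the shared trial `delta`.}
#'   \item{A (autoregressive)}{`z_1 = alpha`;
#'     `z_t = r(y_{t-1}) + beta + gamma * [t - 1 = d]` for `t > 1`, where `r`
#'     is the identity for the additive N family and the logarithm otherwise.
#'     The dishabituation term fires exactly on the first test trial.}
#' }
#' Trial indices are 1-based and the Iverson brackets use the strict/equality
#' comparisons exactly as written above.
#'
#' @return `lt_structures()` returns the three structure codes `"T"`, `"Q"`,
#'   `"A"`.
#' @export
lt_structures <- function() c(T = "trend", Q = "quadratic", A = "ar")

match_structure <- function(structure) {
  if (length(structure) != 1L || !is.character(structure))
    stop("`structure` must be a single character code", call. = FALSE)
  s <- lt_structures()
  if (toupper(structure) %in% names(s)) return(unname(s[toupper(structure)]))
  if (tolower(structure) %in% s) return(tolower(structure))
  stop("unknown structure: ", structure, call. = FALSE)
}

structure_index <- function(structure) {
  match(match_structure(structure), lt_structures()) - 1L
}

check_trial_index <- function(t, d) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 1) || any(t != round(t)))
    stop("trial index `t` must be a positive integer", call. = FALSE)
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d < 1 ||
      d != round(d))
    stop("habituation-trial count `d` must be a positive integer",
         call. = FALSE)
  invisible(NULL)
}

#' @rdname lt_structures
#' @param alpha,beta,gamma infant-level offset, slope and dishabituation
#'   parameters.
#' @param d number of habituation trials (positive integer).
#' @param t trial index, 1-based (vectorized).
#' @export
state_trend <- function(alpha, beta, gamma, d, t) {
  check_trial_index(t, d)
  alpha + beta * t + gamma * (t > d)
}

#' @rdname lt_structures
#' @param delta trial index of the looking-time peak, shared across infants.
#' @export
state_quadratic <- function(alpha, beta, gamma, delta, d, t) {
  check_trial_index(t, d)
  alpha + beta * (t - delta)^2 + gamma * (t > d)
}

#' @rdname lt_structures
#' @param prev_lt observed looking time on trial `t - 1` (required for
#'   `t > 1`).
#' @param family family code; decides whether the previous looking time
#'   enters on the seconds scale (N) or on the log scale (all others).
#' @export
state_ar <- function(alpha, beta, gamma, d, t, prev_lt = NULL, family) {
  check_trial_index(t, d)
  if (length(t) != 1L)
    stop("`state_ar` computes one trial at a time", call. = FALSE)
  if (t == 1) return(alpha)
  if (is.null(prev_lt) || !is.numeric(prev_lt) || !is.finite(prev_lt) ||
      prev_lt <= 0)
    stop("`prev_lt` must be a positive looking time when t > 1",
         call. = FALSE)
  fam <- match_family(family)
  r <- if (fam == "N") prev_lt else log(prev_lt)
  r + beta + gamma * ((t - 1) == d)
}

#' Model specification
#'
#' One candidate model: a family crossed with a time structure, a pooling
#' scheme and a layout for the dishabituation group effects. Models are
#' addressed by three-letter codes (family, structure, pooling) as in
#' `"GTP"` = gamma / trend / partial pooling or `"NTN"` = truncated normal /
#' trend / no pooling.
#'
#' @param family family code, see [lt_families()].
#' @param structure structure code, see [lt_structures()].
#' @param pooling `"none"` or `"partial"`.
#' @param gamma_effects `"main"` (additive contrast + cohort + trial-count
#'   means for the dishabituation parameter) or `"interaction"` (one mean per
#'   contrast-by-trial-count cell, no cohort term). The interaction layout is
#'   only meaningful with partial pooling.
#' @return an object of class `lt_model_spec`.
#' @export
model_spec <- function(family, structure = "T", pooling = c("none", "partial"),
                       gamma_effects = c("main", "interaction")) {
  pooling <- match.arg(pooling)
  gamma_effects <- match.arg(gamma_effects)
  if (gamma_effects == "interaction" && pooling != "partial")
    stop("the interaction layout requires partial pooling", call. = FALSE)
  structure(class = "lt_model_spec",
            list(family = match_family(family),
                 structure = match_structure(structure),
                 pooling = pooling,
                 gamma_effects = gamma_effects))
}

#' @rdname model_spec
#' @param spec an `lt_model_spec`.
#' @export
model_code <- function(spec) {
  stopifnot(inherits(spec, "lt_model_spec"))
  paste0(spec$family,
         names(lt_structures())[match(spec$structure, lt_structures())],
         if (spec$pooling == "partial") "P" else "N")
}

#' @rdname model_spec
#' @param code a three-letter model code such as `"GTP"`.
#' @export
parse_model_code <- function(code, gamma_effects = "main") {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 3L)
    stop("model codes have three letters (family, structure, pooling)",
         call. = FALSE)
  pool <- switch(toupper(substr(code, 3, 3)), N = "none", P = "partial",
                 stop("pooling letter must be N or P", call. = FALSE))
  model_spec(substr(code, 1, 1), substr(code, 2, 2), pool, gamma_effects)
}

#' @export
print.lt_model_spec <- function(x, ...) {
  cat("<lt_model_spec>", model_code(x), "-", x$family, "/", x$structure, "/",
      x$pooling, "pooling /", x$gamma_effects, "gamma effects\n")
  invisible(x)
}

#' Log-likelihood of one infant's trials
#'
#' Sums the family log-density over an infant's ordered trials, with the
#' habituation state computed per the model's time structure. For the
#' autoregressive structure, trial `t`'s state uses the observed looking time
#' on trial `t - 1`, so the trial indices must be consecutive from 1.
#'
#' @param spec an [model_spec()] (the pooling scheme is irrelevant here; the
#'   per-trial likelihood is identical under both).
#' @param params list with elements `alpha`, `beta`, `gamma`, `sigma` and,
#'   for the quadratic structure, `delta`.
#' @param trials ordered positive looking times, trial `t = 1, 2, ...`.
#' @param d number of habituation trials.
#' @param t trial indices (default consecutive from 1). Non-consecutive
#'   indices are allowed for the trend and quadratic structures only.
#' @return total log-likelihood.
#' @export
infant_loglik <- function(spec, params, trials, d, t = seq_along(trials)) {
  stopifnot(inherits(spec, "lt_model_spec"))
  if (length(trials) == 0) stop("`trials` must be non-empty", call. = FALSE)
  check_pos(trials, "trials")
  check_trial_index(t, d)
  z <- switch(spec$structure,
    trend = state_trend(params$alpha, params$beta, params$gamma, d, t),
    quadratic = state_quadratic(params$alpha, params$beta, params$gamma,
                                params$delta, d, t),
    ar = {
      if (!identical(as.integer(t), seq_along(trials)))
        stop("the autoregressive structure requires a consecutive prefix ",
             "of trials", call. = FALSE)
      vapply(seq_along(trials), function(k) {
        state_ar(params$alpha, params$beta, params$gamma, d, t[k],
                 if (k > 1) trials[k - 1], spec$family)
      }, numeric(1))
    })
  sum(lt_logpdf(spec$family, trials, z, params$sigma))
}
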