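#' Sampler configuration
#'
#' Configuration of the built-in No-U-Turn sampler. Two presets are
#' provided: `"full"` runs six chains of 10,000 iterations (6,000 warm-up)
#' thinned by ten, retaining `6 * (10000 - 6000) / 10 = 2400` draws;
#' `"test"` (the default) is a scaled-down configuration of four chains of
#' 2,000 iterations (1,000 warm-up, no thinning) suitable for simulation
#' studies and test suites.
#'
#' @param preset `"test"` or `"full"`; explicit arguments override the
#'   preset.
#' @param chains,iterations,warmup,thin sampler run lengths.
#' @param seed integer seed; every chain derives its RNG stream from it.
#' @param jitter standard deviation of the random initial-value jitter
#'   around the data-informed center, per chain.
#' @param max_depth maximum NUTS tree depth.
#' @return an object of class `lt_sampler_config`.
#' @export
sampler_config <- function(preset = c("test", "full"), chains = NULL,
                           iterations = NULL, warmup = NULL, thin = NULL,
                           seed = 1L, jitter = 0.4, max_depth = 10L) {
  preset <- match.arg(preset)
  def <- if (preset == "full")
    list(chains = 6L, iterations = 10000L, warmup = 6000L, thin = 10L)
  else list(chains = 4L, iterations = 2000L, warmup = 1000L, thin = 1L)
  cfg <- list(preset = preset,
              chains = as.integer(chains %||% def$chains),
              iterations = as.integer(iterations %||% def$iterations),
              warmup = as.integer(warmup %||% def$warmup),
              thin = as.integer(thin %||% def$thin),
              seed = as.integer(seed), jitter = jitter,
              max_depth = as.integer(max_depth))
  if (cfg$warmup >= cfg$iterations)
    stop("`warmup` must be smaller than `iterations`", call. = FALSE)
  if (cfg$chains < 1 || cfg$thin < 1) stop("invalid sampler configuration",
                                           call. = FALSE)
  class(cfg) <- "lt_sampler_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname sampler_config
#' @param config an `lt_sampler_config`.
#' @return `retained_draws()` gives the number of post-warm-up draws the
#'   configuration retains across chains.
#' @export
retained_draws <- function(config) {
  with(config, chains * ((iterations - warmup + thin - 1L) %/% thin))
}

#' Prior settings
#'
#' Weakly-informative defaults used by both pooling schemes: population
#' means (and the no-pooling infant parameters) are normal with mean 0 and
#' standard deviation `mu_sd` on their native scale (seconds for the N and E
#' families, log-seconds otherwise); population scales and the nuisance
#' `sigma` are half-normal with scale `scale_sd`; the shared quadratic peak
#' `delta` is normal.
#'
#' @param mu_sd standard deviation of the mean priors (default 10).
#' @param scale_sd scale of the half-normal priors on scales (default 5).
#' @param delta_mean,delta_sd prior of the quadratic peak trial (default
#'   centered at 1).
#' @return a list of prior settings.
#' @export
lt_priors <- function(mu_sd = 10, scale_sd = 5, delta_mean = 1,
                      delta_sd = 2) {
  list(mu_sd = mu_sd, scale_sd = scale_sd, delta_mean = delta_mean,
       delta_sd = delta_sd)
}

# previous-trial predictor for the autoregressive structure
ar_prev_r <- function(family, y, t) {
  r <- rep(NA_real_, length(y))
  if (length(y) > 1) {
    prev <- y[seq_len(length(y) - 1)]
    r[-1] <- if (match_family(family) == "N") prev else log(prev)
  }
  r[is.na(r)] <- 0 # unused at t = 1
  r
}

# data-informed center of the location parameter
family_location_center <- function(family, y) {
  switch(match_family(family),
         N = mean(y), E = log(mean(y)),
         mean(log(y)))
}

family_lsigma_center <- function(family, y) {
  switch(match_family(family),
         N = log(stats::sd(y) + 0.25), E = log(stats::sd(y) + 0.25),
         L = log(stats::sd(log(y)) + 0.1), W = 0, G = log(2))
}

#' Fit the no-pooling model for one infant
#'
#' Samples the posterior of `(alpha, beta, gamma, sigma)` (plus `delta` for
#' the quadratic structure) for a single infant's trials, under the priors of
#' [lt_priors()]. Convergence is gated at split R-hat < 1.1 on every
#' variable; a non-converged fit is returned with `converged = FALSE` rather
#' than an error, mirroring the reporting rule that drops such fits from
#' comparisons.
#'
#' @param spec an [model_spec()] with `pooling = "none"`.
#' @param y ordered positive looking times.
#' @param d number of habituation trials.
#' @param config an [sampler_config()].
#' @param prior an [lt_priors()] list.
#' @param t trial indices (default consecutive; used to censor trials for
#'   the trend structures).
#' @return an `lt_posterior`.
#' @export
fit_no_pooling <- function(spec, y, d, config = sampler_config(),
                           prior = lt_priors(), t = seq_along(y)) {
  stopifnot(inherits(spec, "lt_model_spec"))
  if (spec$pooling != "none")
    stop("`spec` must have pooling = \"none\"", call. = FALSE)
  check_pos(y, "y")
  check_trial_index(t, d)
  if (length(y) < 4)
    stop("the no-pooling model needs at least 4 trials", call. = FALSE)
  quad <- spec$structure == "quadratic"
  center <- c(family_location_center(spec$family, y), 0, 0,
              family_lsigma_center(spec$family, y), if (quad) 1)
  res <- .nuts_nopool(y, as.integer(t), ar_prev_r(spec$family, y, t),
                      as.integer(d), family_index(spec$family),
                      structure_index(spec$structure), prior, center,
                      config$jitter, config$chains, config$iterations,
                      config$warmup, config$thin, config$seed,
                      config$max_depth)
  draws <- res$draws
  out <- cbind(alpha = draws[, 1], beta = draws[, 2], gamma = draws[, 3],
               sigma = exp(draws[, 4]))
  if (quad) out <- cbind(out, delta = draws[, 5])
  new_lt_posterior(out, res$chain, spec, config,
                   divergent = sum(res$divergent), prior = prior)
}

# --- hierarchical parameter packing (mirrors src/lookhab.cpp) ---------------

# Gram-Schmidt orthonormal basis whose leading columns span `flats`
ortho_basis <- function(k, flats = NULL) {
  M <- cbind(flats, diag(k))
  Q <- matrix(0, k, 0)
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    if (ncol(Q) > 0) v <- v - Q %*% crossprod(Q, v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) Q <- cbind(Q, v / nv)
    if (ncol(Q) == k) break
  }
  unname(Q)
}

# Rotations that isolate the prior-only flat directions of the redundant
# additive group-mean decomposition (mu_b + mu_c leaves all sums unchanged
# when a constant moves between the blocks). The iid normal prior is
# rotation-invariant, so sampling in the rotated basis leaves the model
# unchanged while removing the long prior ridge from the likelihood-informed
# coordinates.
hier_rotations <- function(layout) {
  flat6 <- matrix(c(1, 1, 1, -1, -1, -1), 6)
  Qa <- ortho_basis(6, flat6)
  Qg <- if (layout == "main")
    ortho_basis(10, cbind(c(1, 1, 1, -1, -1, -1, 0, 0, 0, 0),
                          c(1, 1, 1, 0, 0, 0, -1, -1, -1, -1)))
  else diag(12)
  list(Qa = Qa, Qg = Qg)
}

hier_packing <- function(layout, pool_sigma, scales_free, quadratic, ids) {
  gl <- if (layout == "main") 10L else 12L
  os <- 12L + gl
  oh <- os + if (scales_free) 3L else 0L
  od <- oh + if (pool_sigma) 2L else 0L
  orw <- od + if (quadratic) 1L else 0L
  list(gl = gl, o_scales = os, o_sighyp = oh, o_delta = od, o_raw = orw,
       dim = orw + 4L * length(ids))
}

#' Fit the partial-pooling (hierarchical) model
#'
#' Samples the joint posterior of all infant-level and population-level
#' parameters of the hierarchy: `alpha_i ~ N(mu^a_b + mu^a_c, sigma^a)`,
#' `beta_i ~ N(mu^b_b + mu^b_c, sigma^b)` and, under the main-effects layout,
#' `gamma_i ~ N(mu^g_b + mu^g_c + mu^g_d, sigma^g)`; the interaction layout
#' replaces the dishabituation means by one mean per contrast-by-trial-count
#' cell, `gamma_i ~ N(mu^g_{b,d}, sigma^g)`. The per-trial likelihood is
#' identical to the no-pooling model's. The nuisance parameters are pooled
#' lognormally by default (`log sigma_i ~ N(mu, tau)`).
#'
#' The sampler works on a non-centered parametrization; reported draws are
#' the population means, scales, hyper-parameters and the implied
#' infant-level `alpha[i]`, `beta[i]`, `gamma[i]`, `sigma[i]`.
#'
#' @param spec an [model_spec()] with `pooling = "partial"`.
#' @param data an `lt_dataset` (each reported group needs at least two
#'   infants for its mean to be identified).
#' @param config an [sampler_config()].
#' @param prior an [lt_priors()] list.
#' @param pool_sigma pool the nuisance parameters hierarchically (default
#'   TRUE); when FALSE each `sigma_i` gets an independent half-normal prior.
#' @param fixed_scales optional numeric(3): fixes `(sigma^a, sigma^b,
#'   sigma^g)` instead of estimating them (large values disable pooling).
#' @param censor_trial optional trial index removed from every infant's
#'   likelihood (trend/quadratic structures only); used for censored-trial
#'   prediction.
#' @return an `lt_posterior`.
#' @export
fit_partial_pooling <- function(spec, data, config = sampler_config(),
                                prior = lt_priors(), pool_sigma = TRUE,
                                fixed_scales = NULL, censor_trial = NULL) {
  stopifnot(inherits(spec, "lt_model_spec"))
  if (spec$pooling != "partial")
    stop("`spec` must have pooling = \"partial\"", call. = FALSE)
  infants <- dataset_infants(data)
  if (length(infants) < 2) stop("need at least 2 infants", call. = FALSE)
  if (!all(vapply(infants, `[[`, integer(1), "d") %in% hab_trial_levels()))
    stop("partial pooling expects habituation-trial counts in {1, 3, 5, 7}",
         call. = FALSE)
  if (!is.null(censor_trial) && spec$structure == "ar")
    stop("censoring is not supported for the autoregressive structure",
         call. = FALSE)

  ids <- vapply(infants, `[[`, character(1), "id")
  b <- match(vapply(infants, `[[`, character(1), "contrast"),
             contrast_levels()) - 1L
  cc <- match(vapply(infants, `[[`, character(1), "cohort"),
              cohort_levels()) - 1L
  dval <- vapply(infants, `[[`, integer(1), "d")
  dlev <- match(dval, hab_trial_levels()) - 1L
  if (anyNA(b) || anyNA(cc)) stop("unknown contrast or cohort label",
                                  call. = FALSE)

  y <- t_idx <- inf <- prev <- NULL
  for (i in seq_along(infants)) {
    yi <- infants[[i]]$y
    ti <- infants[[i]]$t
    pr <- ar_prev_r(spec$family, yi, ti)
    if (!is.null(censor_trial)) {
      keep <- ti != censor_trial
      yi <- yi[keep]; pr <- pr[keep]; ti <- ti[keep]
    }
    y <- c(y, yi); t_idx <- c(t_idx, ti); prev <- c(prev, pr)
    inf <- c(inf, rep(i - 1L, length(yi)))
  }

  quad <- spec$structure == "quadratic"
  scales_free <- is.null(fixed_scales)
  pk <- hier_packing(spec$gamma_effects, pool_sigma, scales_free, quad, ids)

  rot <- hier_rotations(spec$gamma_effects)
  loc <- family_location_center(spec$family, y)
  lsig <- family_lsigma_center(spec$family, y)
  center <- numeric(pk$dim)
  center[1:6] <- crossprod(rot$Qa, c(rep(loc, 3), rep(0, 3)))  # u_alpha
  if (scales_free) center[pk$o_scales + 1:3] <- log(c(0.3, 0.05, 0.2))
  if (pool_sigma) center[pk$o_sighyp + 1:2] <- c(lsig, log(0.2))
  else center[pk$o_raw + 3L * length(ids) + seq_along(ids)] <- lsig
  if (quad) center[pk$o_delta + 1L] <- prior$delta_mean

  res <- .nuts_hier(y, as.integer(t_idx), prev, inf, b, cc, dlev,
                    as.integer(dval), family_index(spec$family),
                    structure_index(spec$structure),
                    if (spec$gamma_effects == "main") 0L else 1L,
                    pool_sigma,
                    if (scales_free) numeric(0) else as.numeric(fixed_scales),
                    rot$Qa, rot$Qg,
                    prior, center, config$jitter, config$chains,
                    config$iterations, config$warmup, config$thin,
                    config$seed, config$max_depth)

  out <- hier_report_draws(res$draws, spec, pk, rot, pool_sigma, scales_free,
                           fixed_scales, b, cc, dlev, ids)
  new_lt_posterior(out, res$chain, spec, config,
                   divergent = sum(res$divergent), prior = prior,
                   infants = data.frame(infant_id = ids,
                                        contrast = contrast_levels()[b + 1L],
                                        cohort = cohort_levels()[cc + 1L],
                                        n_hab_trials = dval,
                                        stringsAsFactors = FALSE))
}

# transform raw sampler draws into reported (named) variables
hier_report_draws <- function(draws, spec, pk, rot, pool_sigma, scales_free,
                              fixed_scales, b, cc, dlev, ids) {
  n <- length(ids)
  bl <- contrast_levels(); cl <- cohort_levels(); dl <- hab_trial_levels()
  cols <- list()
  nm <- function(base, lv) paste0(base, "[", lv, "]")
  pop_names <- c(nm("mu_alpha_b", bl), nm("mu_alpha_c", cl),
                 nm("mu_beta_b", bl), nm("mu_beta_c", cl))
  # interaction cells in b-major order: luminance 1,3,5,7, color 1,3,5,7, ...
  gamma_names <- if (spec$gamma_effects == "main")
    c(nm("mu_gamma_b", bl), nm("mu_gamma_c", cl), nm("mu_gamma_d", dl))
  else nm("mu_gamma_bd", as.vector(t(outer(bl, dl, paste, sep = ","))))
  # rotate the sampled u coordinates back to the population means
  pop <- cbind(draws[, 1:6, drop = FALSE] %*% t(rot$Qa),
               draws[, 7:12, drop = FALSE] %*% t(rot$Qa),
               draws[, 12L + seq_len(pk$gl), drop = FALSE] %*% t(rot$Qg))
  colnames(pop) <- c(pop_names, gamma_names)
  cols$pop <- pop

  if (scales_free) {
    sc <- exp(draws[, pk$o_scales + 1:3, drop = FALSE])
  } else {
    sc <- matrix(rep(fixed_scales, each = nrow(draws)), ncol = 3)
  }
  colnames(sc) <- c("sigma_alpha", "sigma_beta", "sigma_gamma")
  cols$sc <- sc

  if (pool_sigma) {
    hy <- cbind(mu_logsigma = draws[, pk$o_sighyp + 1L],
                tau_logsigma = exp(draws[, pk$o_sighyp + 2L]))
    cols$hy <- hy
  }
  if (spec$structure == "quadratic")
    cols$delta <- cbind(delta = draws[, pk$o_delta + 1L])

  orw <- pk$o_raw
  araw <- draws[, orw + seq_len(n), drop = FALSE]
  braw <- draws[, orw + n + seq_len(n), drop = FALSE]
  graw <- draws[, orw + 2L * n + seq_len(n), drop = FALSE]
  sraw <- draws[, orw + 3L * n + seq_len(n), drop = FALSE]

  alpha <- pop[, 0L + b + 1L, drop = FALSE] + pop[, 3L + cc + 1L] +
    sc[, 1] * araw
  beta <- pop[, 6L + b + 1L, drop = FALSE] + pop[, 9L + cc + 1L] +
    sc[, 2] * braw
  gmean <- if (spec$gamma_effects == "main")
    pop[, 12L + b + 1L, drop = FALSE] + pop[, 15L + cc + 1L] +
      pop[, 18L + dlev + 1L]
  else pop[, 12L + 4L * b + dlev + 1L, drop = FALSE]
  gamma <- gmean + sc[, 3] * graw
  sigma <- if (pool_sigma) exp(cols$hy[, 1] + cols$hy[, 2] * sraw)
  else exp(sraw)
  colnames(alpha) <- nm("alpha", ids)
  colnames(beta) <- nm("beta", ids)
  colnames(gamma) <- nm("gamma", ids)
  colnames(sigma) <- nm("sigma", ids)
  do.call(cbind, c(unname(cols), list(alpha, beta, gamma, sigma)))
}

#' Fit one model to a full dataset
#'
#' Convenience dispatcher: for a partial-pooling spec this is
#' [fit_partial_pooling()]; for a no-pooling spec the model is fitted
#' separately to every infant with at least `min_trials` trials (per-infant
#' seeds derived from `config$seed`) and a named list of posteriors is
#' returned.
#'
#' @inheritParams fit_partial_pooling
#' @param min_trials minimum trials an infant needs for a separate fit
#'   (default 4).
#' @return an `lt_posterior`, or a named list of them (class
#'   `lt_posterior_list`) for no pooling.
#' @export
fit_dataset <- function(spec, data, config = sampler_config(),
                        prior = lt_priors(), censor_trial = NULL,
                        min_trials = 4L, ...) {
  if (spec$pooling == "partial")
    return(fit_partial_pooling(spec, data, config, prior,
                               censor_trial = censor_trial, ...))
  infants <- dataset_infants(data)
  fits <- list()
  for (i in seq_along(infants)) {
    inf <- infants[[i]]
    y <- inf$y; tt <- inf$t
    if (!is.null(censor_trial)) {
      if (spec$structure == "ar")
        stop("censoring is not supported for the autoregressive structure",
             call. = FALSE)
      keep <- tt != censor_trial
      y <- y[keep]; tt <- tt[keep]
    }
    if (length(y) < min_trials) next
    cfg_i <- config
    cfg_i$seed <- config$seed + 13L * i
    fits[[inf$id]] <- fit_no_pooling(spec, y, inf$d, cfg_i, prior, t = tt)
  }
  structure(fits, class = "lt_posterior_list", spec = spec)
}

# --- posterior container ----------------------------------------------------

new_lt_posterior <- function(draws, chain, spec, config, divergent = 0L,
                             prior = NULL, infants = NULL) {
  stopifnot(is.matrix(draws), length(chain) == nrow(draws))
  rh <- apply_rhat(draws, chain)
  obj <- list(draws = draws, chain = as.integer(chain), spec = spec,
              config = config, prior = prior, rhat = rh,
              converged = all(is.finite(rh) & rh < 1.1),
              divergent = divergent, infants = infants,
              seed = config$seed)
  class(obj) <- "lt_posterior"
  obj
}

apply_rhat <- function(draws, chain) {
  vapply(seq_len(ncol(draws)), function(j) {
    suppressWarnings(rhat(split(draws[, j], chain)))
  }, numeric(1)) |> stats::setNames(colnames(draws))
}

#' Split potential-scale-reduction statistic (R-hat)
#'
#' The split-chain variant of the potential scale reduction statistic,
#' computed on retained (post-thinning) draws: each chain is split in half,
#' and `R-hat = sqrt(((n - 1)/n * W + B/n) / W)` with `B`/`W` the between-
#' and within-half variances. Values near 1 indicate convergence; fits are
#' gated at R-hat < 1.1. Because halves are compared, permuting draws within
#' a chain can change the value (a trending chain is detected through its
#' half-means).
#'
#' @param chains a list of numeric vectors (one per chain, at least 2 chains
#'   of at least 4 draws), or a matrix with one column per chain.
#' @return R-hat; `NA` with a warning when the draws have zero variance.
#' @export
rhat <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2)
  if (!is.list(chains) || length(chains) < 2)
    stop("need at least 2 chains", call. = FALSE)
  if (any(lengths(chains) < 4))
    stop("need at least 4 draws per chain", call. = FALSE)
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(x) x[seq_len(n)])
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  w <- mean(vars)
  b <- n * stats::var(means)
  if (!is.finite(w) || w <= 0) {
    warning("zero within-chain variance; R-hat undefined")
    return(NA_real_)
  }
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Posterior summaries
#'
#' Empirical quantiles of the retained draws of one variable: the median and
#' central 50 and 95 percent intervals by default (the errorbar convention
#' used throughout the reports).
#'
#' @param posterior an `lt_posterior`.
#' @param variable variable name (see `colnames(posterior$draws)`).
#' @param probs quantile probabilities.
#' @return named numeric vector of quantiles (R's default type-7 rule).
#' @export
posterior_summary <- function(posterior,
                              variable,
                              probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  stopifnot(inherits(posterior, "lt_posterior"))
  if (!variable %in% colnames(posterior$draws))
    stop("unknown variable: ", variable, call. = FALSE)
  stats::quantile(posterior$draws[, variable], probs = probs, names = TRUE)
}

#' @export
print.lt_posterior <- function(x, ...) {
  cat("<lt_posterior>", model_code(x$spec), "-", ncol(x$draws), "variables,",
      nrow(x$draws), "retained draws,", max(x$chain), "chains\n")
  cat("  converged:", x$converged,
      sprintf("(max R-hat %.3f)", suppressWarnings(max(x$rhat, na.rm = TRUE))),
      "- divergent transitions:", x$divergent, "\n")
  invisible(x)
}

#' Per-infant posterior medians
#'
#' Extracts the per-infant marginal posterior medians of `(alpha, beta,
#' gamma, sigma)` (and `delta`, when present) as a data.frame, from either a
#' partial-pooling posterior or a list of per-infant no-pooling posteriors.
#' This is the input expected by [anova_table()] and [correlation_table()]
#' (after merging in the condition labels) and the parameter plug-in used by
#' the evaluation metrics.
#'
#' @param fit an `lt_posterior` (partial pooling) or `lt_posterior_list`
#'   (no pooling).
#' @return data.frame with one row per infant and a `converged` flag.
#' @export
median_infant_params <- function(fit) {
  if (inherits(fit, "lt_posterior_list")) {
    rows <- lapply(names(fit), function(id) {
      p <- fit[[id]]
      med <- apply(p$draws, 2, stats::median)
      data.frame(infant_id = id, alpha = med[["alpha"]], beta = med[["beta"]],
                 gamma = med[["gamma"]], sigma = med[["sigma"]],
                 delta = if ("delta" %in% names(med)) med[["delta"]] else NA,
                 converged = p$converged, stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  stopifnot(inherits(fit, "lt_posterior"))
  ids <- fit$infants$infant_id
  med <- apply(fit$draws, 2, stats::median)
  get <- function(base) unname(med[paste0(base, "[", ids, "]")])
  data.frame(infant_id = ids, alpha = get("alpha"), beta = get("beta"),
             gamma = get("gamma"), sigma = get("sigma"),
             delta = if ("delta" %in% names(med)) med[["delta"]] else NA,
             converged = fit$converged, stringsAsFactors = FALSE)
}

#' Serialize a posterior
#'
#' Writes the retained draws as long-format CSV (`chain`, `iteration`,
#' `variable`, `value`) with a JSON diagnostics sidecar (`<path>.json`)
#' holding the model code, sampler configuration, seed, per-variable R-hat
#' and convergence flag.
#'
#' @param posterior an `lt_posterior`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(posterior, path) {
  stopifnot(inherits(posterior, "lt_posterior"))
  d <- posterior$draws
  it <- stats::ave(seq_len(nrow(d)), posterior$chain, FUN = seq_along)
  long <- data.frame(chain = rep(posterior$chain, ncol(d)),
                     iteration = rep(it, ncol(d)),
                     variable = rep(colnames(d), each = nrow(d)),
                     value = as.vector(d))
  utils::write.csv(long, path, row.names = FALSE)
  meta <- list(model = model_code(posterior$spec),
               gamma_effects = posterior$spec$gamma_effects,
               config = unclass(posterior$config),
               seed = posterior$seed, rhat = as.list(posterior$rhat),
               converged = posterior$converged,
               divergent = posterior$divergent)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
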