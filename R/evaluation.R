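#' Data log-likelihood at the posterior medians
#'
#' The data likelihood of one model, measured by plugging the per-infant
#' marginal posterior medians of `(alpha, beta, gamma, sigma)` (and `delta`)
#' into [infant_loglik()] and summing over infants. Non-converged per-infant
#' fits are skipped, mirroring the reporting rule; their ids are attached as
#' the `"skipped"` attribute.
#'
#' @param spec an [model_spec()].
#' @param fit the fitted posterior: an `lt_posterior` (partial pooling) or a
#'   named `lt_posterior_list` (no pooling, one posterior per infant).
#' @param data the `lt_dataset` the model was fitted to.
#' @return total log-likelihood (numeric scalar).
#' @export
loglik_at_medians <- function(spec, fit, data) {
  params <- median_infant_params(fit)
  infants <- dataset_infants(data)
  names(infants) <- vapply(infants, `[[`, character(1), "id")
  missing_ids <- setdiff(params$infant_id, names(infants))
  if (length(missing_ids))
    stop("fitted infants absent from data: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  keep <- params$converged
  total <- 0
  for (k in which(keep)) {
    inf <- infants[[params$infant_id[k]]]
    p <- list(alpha = params$alpha[k], beta = params$beta[k],
              gamma = params$gamma[k], sigma = params$sigma[k],
              delta = params$delta[k])
    total <- total + infant_loglik(spec, p, inf$y, inf$d, inf$t)
  }
  structure(total, skipped = params$infant_id[!keep])
}

#' Posterior-predictive mean absolute error
#'
#' For every infant and trial, draws `n_samples` looking times from the
#' model at the per-infant median parameters, computes the mean absolute
#' deviation from the observed looking time, and averages over trials within
#' infants. Reported as the across-infant error distribution (median, 25-75
#' and 2.5-97.5 percentile bands) plus the grand mean across infants.
#'
#' @inheritParams loglik_at_medians
#' @param n_samples predictive draws per trial (default 1000).
#' @param seed integer seed making the Monte-Carlo draws reproducible.
#' @return list with `per_infant` (named vector of per-infant MAEs in
#'   seconds), `bands` (2.5/25/50/75/97.5 percentiles across infants) and
#'   `grand_mean`.
#' @export
mean_absolute_error <- function(spec, fit, data, n_samples = 1000L,
                                seed = 1L) {
  params <- median_infant_params(fit)
  params <- params[params$converged, , drop = FALSE]
  infants <- dataset_infants(data)
  names(infants) <- vapply(infants, `[[`, character(1), "id")
  with_seed(seed, {
    mae <- vapply(seq_len(nrow(params)), function(k) {
      inf <- infants[[params$infant_id[k]]]
      per_trial <- vapply(seq_along(inf$y), function(j) {
        z <- trial_state(spec, params[k, ], inf, j)
        draws <- family_sample(spec$family, n_samples, z, params$sigma[k])
        mean(abs(draws - inf$y[j]))
      }, numeric(1))
      mean(per_trial)
    }, numeric(1))
    names(mae) <- params$infant_id
    list(per_infant = mae,
         bands = stats::quantile(mae, c(0.025, 0.25, 0.5, 0.75, 0.975)),
         grand_mean = mean(mae))
  })
}

# habituation state of one observed trial under median parameters
trial_state <- function(spec, p, inf, j) {
  t <- inf$t[j]
  switch(spec$structure,
    trend = state_trend(p$alpha, p$beta, p$gamma, inf$d, t),
    quadratic = state_quadratic(p$alpha, p$beta, p$gamma, p$delta, inf$d, t),
    ar = state_ar(p$alpha, p$beta, p$gamma, inf$d, t,
                  if (j > 1) inf$y[j - 1], spec$family))
}

#' Censored-fifth-trial prediction
#'
#' Evaluates predictive performance by refitting the model with the fifth
#' trial removed from every qualifying infant's likelihood and then (a)
#' evaluating the log-density of the held-out looking times at the median
#' parameter estimates, and (b) computing the absolute error between the
#' held-out looking times and the model's prediction at trial 5. Both the
#' error of the posterior-predictive mean prediction and the mean draw-wise
#' error are reported. Only the trend and quadratic structures are
#' supported; the autoregressive state at trial 5 would need the censored
#' trial-4..5 transition.
#'
#' Infants without a fifth trial are retained in the fitting but excluded
#' from the predictive metrics.
#'
#' @inheritParams loglik_at_medians
#' @param config an [sampler_config()] for the refit.
#' @param censor_trial held-out trial index (default 5).
#' @param n_samples posterior-predictive draws per infant.
#' @param seed seed for the predictive draws.
#' @param ... passed on to [fit_dataset()].
#' @return list with `predictive_loglik`, `abs_error_mean_prediction`,
#'   `abs_error_drawwise`, per-infant vectors, the number of evaluated
#'   infants and the refitted posterior.
#' @export
censored_prediction <- function(spec, data, config = sampler_config(),
                                censor_trial = 5L, n_samples = 1000L,
                                seed = 1L, ...) {
  if (spec$structure == "ar")
    stop("censored prediction is not supported for the autoregressive ",
         "structure", call. = FALSE)
  fit <- fit_dataset(spec, data, config, censor_trial = censor_trial, ...)
  params <- median_infant_params(fit)
  params <- params[params$converged, , drop = FALSE]
  infants <- dataset_infants(data)
  names(infants) <- vapply(infants, `[[`, character(1), "id")
  held <- vapply(params$infant_id, function(id)
    censor_trial %in% infants[[id]]$t, logical(1))
  eval_ids <- params$infant_id[held]
  ll <- err_mean <- err_draw <- stats::setNames(numeric(length(eval_ids)),
                                                eval_ids)
  with_seed(seed, {
    for (id in eval_ids) {
      inf <- infants[[id]]
      k <- match(id, params$infant_id)
      j <- match(censor_trial, inf$t)
      z <- trial_state(spec, params[k, ], inf, j)
      y5 <- inf$y[j]
      ll[id] <- lt_logpdf(spec$family, y5, z, params$sigma[k])
      draws <- family_sample(spec$family, n_samples, z, params$sigma[k])
      err_mean[id] <- abs(mean(draws) - y5)
      err_draw[id] <- mean(abs(draws - y5))
    }
  })
  list(predictive_loglik = sum(ll),
       abs_error_mean_prediction = mean(err_mean),
       abs_error_drawwise = mean(err_draw),
       per_infant_loglik = ll, per_infant_abs_error = err_mean,
       n_evaluated = length(eval_ids), fit = fit)
}

#' Fit report for one model
#'
#' Bundles the three comparison metrics of one fitted model: total data
#' log-likelihood at the posterior medians, the posterior-predictive
#' mean-absolute-error distribution, and (optionally) the censored-trial
#' predictive metrics.
#'
#' @inheritParams mean_absolute_error
#' @param prediction optional result of [censored_prediction()].
#' @return an `lt_fit_report` list.
#' @export
fit_report <- function(spec, fit, data, n_samples = 1000L, seed = 1L,
                       prediction = NULL) {
  mae <- mean_absolute_error(spec, fit, data, n_samples, seed)
  rep <- list(model = model_code(spec),
              loglik = as.numeric(loglik_at_medians(spec, fit, data)),
              mae_bands = mae$bands, mae_grand_mean = mae$grand_mean,
              predictive_loglik = prediction$predictive_loglik,
              predictive_abs_error = prediction$abs_error_mean_prediction)
  class(rep) <- "lt_fit_report"
  rep
}

#' @export
print.lt_fit_report <- function(x, ...) {
  cat("<lt_fit_report>", x$model, "- loglik", format(x$loglik, digits = 6),
      "- MAE", format(x$mae_grand_mean, digits = 4), "s\n")
  invisible(x)
}

#' Model-comparison table
#'
#' @param reports a list of [fit_report()] results.
#' @return data.frame with one row per model code and the comparison
#'   metrics.
#' @export
comparison_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(model = r$model, loglik = r$loglik,
               mae_median = unname(r$mae_bands[["50%"]]),
               mae_q25 = unname(r$mae_bands[["25%"]]),
               mae_q75 = unname(r$mae_bands[["75%"]]),
               mae_grand_mean = r$mae_grand_mean,
               predictive_loglik = r$predictive_loglik %||% NA_real_,
               predictive_abs_error = r$predictive_abs_error %||% NA_real_,
               stringsAsFactors = FALSE)))
}
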