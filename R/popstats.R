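#' Omnibus ANOVA on per-infant parameter estimates
#'
#' Applies an omnibus ANOVA to the per-infant posterior medians obtained
#' from converged no-pooling fits, with the factor terms restricted to the
#' theoretically plausible effects: the offset and slope get stimulus
#' contrast (S), age cohort (A) and their interaction; the dishabituation
#' parameter additionally gets the number of habituation trials (T) and all
#' its interactions. Type-II sums of squares are used for the unbalanced
#' design.
#'
#' @param params data.frame with columns `contrast`, `cohort`,
#'   `n_hab_trials` and the parameter columns named in `design` (typically
#'   the output of [median_infant_params()] merged with the condition
#'   labels); a logical `converged` column, when present, filters the rows.
#' @param design named list mapping parameter name to a character vector of
#'   model terms built from `S`, `A`, `T` (defaults to the layout described
#'   above for `alpha`, `beta`, `gamma`).
#' @param alpha_level significance level for the star flag (default 0.05).
#' @return data.frame of class `lt_anova_table` with columns `parameter`,
#'   `term`, `F`, `df1`, `df2`, `p`, `significant`.
#' @export
anova_table <- function(params,
                        design = list(alpha = c("S", "A", "S:A"),
                                      beta = c("S", "A", "S:A"),
                                      gamma = c("S", "A", "S:A", "T", "T:S",
                                                "T:A", "T:S:A")),
                        alpha_level = 0.05) {
  stopifnot(is.data.frame(params))
  if ("converged" %in% names(params))
    params <- params[params$converged, , drop = FALSE]
  frame <- data.frame(S = droplevels(factor(params$contrast)),
                      A = droplevels(factor(params$cohort)),
                      T = droplevels(factor(params$n_hab_trials)))
  rows <- list()
  for (par in names(design)) {
    if (!par %in% names(params))
      stop("parameter column missing: ", par, call. = FALSE)
    terms <- design[[par]]
    dat <- cbind(frame, .y = params[[par]])
    fml <- stats::reformulate(terms, response = ".y")
    fit <- stats::lm(fml, data = dat)
    a2 <- car::Anova(fit, type = 2)
    res_df <- a2["Residuals", "Df"]
    res_ms <- a2["Residuals", "Sum Sq"] / res_df
    if (!is.finite(res_ms) || res_ms <= 0)
      stop("zero residual variance; F undefined for parameter ", par,
           call. = FALSE)
    # report under the requested term labels (lm orders interaction factors
    # by model-frame position, e.g. "S:T" for the requested "T:S")
    canon <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                                function(p) paste(sort(p), collapse = ":"),
                                character(1))
    fitted_terms <- setdiff(rownames(a2), "Residuals")
    for (term in terms) {
      row <- fitted_terms[canon(fitted_terms) == canon(term)]
      if (length(row) != 1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, term = term, F = a2[row, "F value"],
        df1 = a2[row, "Df"], df2 = res_df, p = a2[row, "Pr(>F)"],
        significant = is.finite(a2[row, "Pr(>F)"]) &&
          a2[row, "Pr(>F)"] < alpha_level,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("lt_anova_table", "data.frame")
  out
}

#' Pearson correlations between per-infant parameter estimates
#'
#' The six pairwise correlations between the per-infant median estimates of
#' `alpha`, `beta`, `gamma` and `sigma` across infants, in the order
#' `r_alpha_sigma`, `r_beta_sigma`, `r_gamma_sigma`, `r_alpha_beta`,
#' `r_alpha_gamma`, `r_beta_gamma`.
#'
#' @param params data.frame with columns `alpha`, `beta`, `gamma`, `sigma`
#'   (and optionally `converged`, used to filter rows).
#' @return named numeric vector of the six correlations; entries are `NA`
#'   (with a warning) when a parameter has zero variance.
#' @export
correlation_table <- function(params) {
  if ("converged" %in% names(params))
    params <- params[params$converged, , drop = FALSE]
  if (nrow(params) < 4) stop("need at least 4 infants", call. = FALSE)
  pairs <- list(r_alpha_sigma = c("alpha", "sigma"),
                r_beta_sigma = c("beta", "sigma"),
                r_gamma_sigma = c("gamma", "sigma"),
                r_alpha_beta = c("alpha", "beta"),
                r_alpha_gamma = c("alpha", "gamma"),
                r_beta_gamma = c("beta", "gamma"))
  vapply(pairs, function(pr) {
    x <- params[[pr[1]]]; y <- params[[pr[2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero variance in ", paste(pr, collapse = "/"),
              "; correlation undefined")
      return(NA_real_)
    }
    stats::cor(x, y)
  }, numeric(1))
}

#' Main-effect summaries from a partial-pooling posterior
#'
#' For each displayed group (age cohorts 4M/7M/10M, contrasts
#' luminance/color/orientation and, for the dishabituation parameter,
#' habituation-trial counts 1/3/5/7) summarizes the identified group-level
#' sum of the population means. Because the additive decomposition
#' `mu_b + mu_c` is only identified through sums, a displayed group's draw
#' is its own mean plus the average of the other factor's means (draw-wise).
#' For the multiplicative families the slope and dishabituation draws are
#' percent-transformed (draw-wise, before quantiles; the transform is
#' monotone so order statistics commute); the additive N family is reported
#' in seconds.
#'
#' @param posterior a converged partial-pooling `lt_posterior` with the
#'   main-effects layout.
#' @param probs quantiles reported per group.
#' @return data.frame with columns `parameter`, `factor`, `group`, `unit`
#'   and one column per quantile.
#' @export
main_effects_summary <- function(posterior,
                                 probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  stopifnot(inherits(posterior, "lt_posterior"))
  spec <- posterior$spec
  if (spec$gamma_effects != "main")
    stop("main_effects_summary needs the main-effects layout", call. = FALSE)
  d <- posterior$draws
  multiplicative <- spec$family != "N"
  bl <- contrast_levels(); cl <- cohort_levels(); dl <- hab_trial_levels()
  col <- function(base, lv) d[, paste0(base, "[", lv, "]")]
  rowmean <- function(base, lv) rowMeans(d[, paste0(base, "[", lv, "]"),
                                           drop = FALSE])
  rows <- list()
  add_row <- function(parameter, fac, group, draws, transform) {
    unit <- if (!multiplicative) "seconds"
    else if (transform) "percent" else "log-seconds"
    if (multiplicative && transform) draws <- percent_change(draws)
    q <- stats::quantile(draws, probs)
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(parameter = parameter, factor = fac, group = group,
                 unit = unit, stringsAsFactors = FALSE),
      as.data.frame(as.list(q), check.names = FALSE))
  }
  for (par in c("alpha", "beta", "gamma")) {
    base_b <- paste0("mu_", par, "_b")
    base_c <- paste0("mu_", par, "_c")
    transform <- par != "alpha"
    for (b in bl)
      add_row(par, "contrast", b, col(base_b, b) + rowmean(base_c, cl),
              transform)
    for (cc in cl)
      add_row(par, "cohort", cc, col(base_c, cc) + rowmean(base_b, bl),
              transform)
    if (par == "gamma")
      for (dd in dl)
        add_row(par, "n_hab_trials", as.character(dd),
                col("mu_gamma_d", dd) + rowmean(base_b, bl) +
                  rowmean(base_c, cl), transform)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Early-vs-late dishabituation contrast
#'
#' The average contrast between late (5 or 7 habituation trials) and early
#' (1 or 3) presentation of the test trial, computed from the
#' interaction-layout posterior over the luminance and color cells:
#' `(g_B5 + g_B7 - g_B1 - g_B3 + g_C5 + g_C7 - g_C1 - g_C3) / 4`, evaluated
#' per posterior draw on the latent (log) scale and then percent-transformed.
#'
#' @param posterior a partial-pooling `lt_posterior` fitted with
#'   `gamma_effects = "interaction"`.
#' @param probs quantiles of the reported interval (default central 95
#'   percent plus the median).
#' @return named vector: percent-scale quantiles of the contrast.
#' @export
dishabituation_contrast <- function(posterior,
                                    probs = c(0.025, 0.5, 0.975)) {
  stopifnot(inherits(posterior, "lt_posterior"))
  if (posterior$spec$gamma_effects != "interaction")
    stop("dishabituation_contrast needs the interaction layout",
         call. = FALSE)
  d <- posterior$draws
  cell <- function(b, k) {
    nm <- paste0("mu_gamma_bd[", b, ",", k, "]")
    if (!nm %in% colnames(d)) stop("missing cell: ", nm, call. = FALSE)
    d[, nm]
  }
  contrast <- (cell("luminance", 5) + cell("luminance", 7) -
                 cell("luminance", 1) - cell("luminance", 3) +
                 cell("color", 5) + cell("color", 7) -
                 cell("color", 1) - cell("color", 3)) / 4
  stats::quantile(percent_change(contrast), probs)
}

#' Trials to a fixed habituation criterion
#'
#' Under a deterministic multiplicative decrease of `per_trial_decrease` per
#' trial, the smallest trial count `t` with
#' `(1 - per_trial_decrease)^t <= criterion`. With the 7 percent per-trial
#' decrease, ten trials are needed to reach the common 50 percent criterion.
#'
#' @param per_trial_decrease proportion in (0, 1), e.g. 0.07.
#' @param criterion proportion of the initial looking time in (0, 1).
#' @return integer trial count.
#' @export
trials_to_criterion <- function(per_trial_decrease, criterion) {
  check_proportion(per_trial_decrease, "per_trial_decrease")
  check_proportion(criterion, "criterion")
  as.integer(ceiling(log(criterion) / log(1 - per_trial_decrease)))
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1)
    stop("`", name, "` must lie strictly in (0, 1)", call. = FALSE)
}

#' Trials to a running-average habituation criterion
#'
#' The infant-controlled design's criterion compares the mean looking time
#' on the last `window` trials with the mean on the first `window` trials.
#' Under deterministic multiplicative decay `LT_t = (1 - rho)^(t - 1)`, this
#' returns the smallest `t >= window` with
#' `mean(LT[(t - window + 1):t]) <= criterion * mean(LT[1:window])`. With
#' consecutive windows of three trials and a 7 percent decrease the
#' criterion is reached on trial 13.
#'
#' @inheritParams trials_to_criterion
#' @param window trials per running average (default 3).
#' @return integer trial count.
#' @export
running_average_criterion_trials <- function(per_trial_decrease, criterion,
                                             window = 3L) {
  check_proportion(per_trial_decrease, "per_trial_decrease")
  check_proportion(criterion, "criterion")
  if (window < 1 || window != round(window))
    stop("`window` must be a positive integer", call. = FALSE)
  q <- 1 - per_trial_decrease
  lt <- function(t) q^(t - 1)
  first <- mean(lt(seq_len(window)))
  t <- window
  repeat {
    if (mean(lt((t - window + 1):t)) <= criterion * first) return(as.integer(t))
    t <- t + 1
    if (t > 1e6) stop("criterion not reached", call. = FALSE)
  }
}

#' Fisher-transformation confidence-interval half-widths
#'
#' Half-widths of the 95 percent normal-based confidence interval for a
#' Pearson correlation, via the Fisher z-transformation:
#' `tanh(atanh(r) +/- 1.96 / sqrt(n - 3)) - r`. At `r = 0` and the study's
#' n = 301 the half-width is about 0.11 on both sides.
#'
#' @param n sample size (at least 4).
#' @param r correlation, `|r| < 1`.
#' @return named vector `c(lower, upper)` of non-negative half-widths.
#' @export
fisher_ci_halfwidth <- function(n, r = 0) {
  if (!is.numeric(n) || length(n) != 1L || n < 4 || n != round(n))
    stop("`n` must be an integer of at least 4", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || abs(r) >= 1)
    stop("`r` must satisfy |r| < 1", call. = FALSE)
  half <- 1.96 / sqrt(n - 3)
  c(lower = r - tanh(atanh(r) - half), upper = tanh(atanh(r) + half) - r)
}
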