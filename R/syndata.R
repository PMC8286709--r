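#' Age-cohort assignment
#'
#' Maps age in days to the three cohorts used in the study design. The
#' intervals are half-open on the younger cohort's upper edge, so ages 165
#' and 255 belong to the older cohort: 4M = \[117, 165), 7M = \[165, 255),
#' 10M = \[255, 339\].
#'
#' @param age_days integer age(s) in days, between 117 and 339.
#' @return factor with levels `"4M"`, `"7M"`, `"10M"`.
#' @export
assign_cohort <- function(age_days) {
  if (!is.numeric(age_days) || any(!is.finite(age_days)))
    stop("`age_days` must be numeric and finite", call. = FALSE)
  if (any(age_days < 117 | age_days > 339))
    stop("`age_days` must lie in [117, 339]", call. = FALSE)
  cut(age_days, breaks = c(117, 165, 255, 339.5), right = FALSE,
      labels = cohort_levels())
}

cohort_levels <- function() c("4M", "7M", "10M")
contrast_levels <- function() c("luminance", "color", "orientation")
hab_trial_levels <- function() c(1L, 3L, 5L, 7L)

cohort_age_range <- function(cohort) {
  switch(as.character(cohort),
         "4M" = c(117L, 164L), "7M" = c(165L, 254L), "10M" = c(255L, 339L))
}

#' Study-design cell sizes
#'
#' Number of infants per contrast x cohort x habituation-trial-count cell in
#' the study sample after exclusion (301 infants). Used as the default design
#' of the synthetic-data generator.
#'
#' @return data.frame with columns `contrast`, `cohort`, `n_hab_trials`, `n`.
#' @export
study_cell_sizes <- function() {
  n <- c(11, 14, 9, 7, 11, 11, 10, 2, 10, 10, 10, 9,    # luminance
         5, 8, 8, 6, 13, 11, 10, 10, 11, 10, 10, 11,    # color
         1, 7, 1, 1, 10, 12, 9, 6, 6, 10, 6, 5)         # orientation
  expand.grid(n_hab_trials = hab_trial_levels(), cohort = cohort_levels(),
              contrast = contrast_levels(), KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)[, 3:1] |>
    cbind(n = n)
}

#' Synthetic-data generator configuration
#'
#' Defines the population from which synthetic infants are drawn. The
#' defaults emulate the study conditions: a gamma-trend generating model, a
#' mean per-trial looking-time decrease of 7 percent (`mu_beta_b` at
#' `log(0.93)`), initial mean looking times of about 3.7 s in the luminance
#' condition and about 5 s in the color and orientation conditions, a
#' dishabituation that is strongest for the luminance contrast, absent to
#' negative for the orientation contrast, and larger after 5 or 7 habituation
#' trials (the early-vs-late split of `mu_gamma_d` equals a latent contrast
#' of 0.192, i.e. 21.2 percent), and a per-trial dropout hazard calibrated to
#' the study's 16 percent session-exclusion rate.
#'
#' @param cell_sizes data.frame with columns `contrast`, `cohort`,
#'   `n_hab_trials`, `n`; defaults to the study design ([study_cell_sizes()]).
#' @param family,structure generating model (default gamma trend, the
#'   best-fitting model class).
#' @param mu_alpha_b,mu_alpha_c population means of the offset by contrast
#'   (luminance, color, orientation) and cohort (4M, 7M, 10M); an infant's
#'   mean offset is the sum of its two group entries. The defaults solve
#'   `E[sigma_i] * E[exp(alpha_i + beta_i)] = target mean` for targets
#'   3.7 s / 5 s at trial 1; the constant 0.0655 is the lognormal mean
#'   correction `(sigma_log_sd^2 + scale_alpha^2 + scale_beta^2) / 2` for
#'   the default scales.
#' @param mu_beta_b,mu_beta_c population means of the slope.
#' @param mu_gamma_b,mu_gamma_c,mu_gamma_d population means of the
#'   dishabituation parameter by contrast, cohort, and habituation-trial
#'   count (1, 3, 5, 7).
#' @param scale_alpha,scale_beta,scale_gamma between-infant standard
#'   deviations.
#' @param sigma_log_mean,sigma_log_sd mean and sd of `log(sigma_i)` (the
#'   per-infant nuisance parameter is drawn lognormally).
#' @param dropout_hazard probability that a session ends before each trial
#'   after the first.
#' @param n_test_trials planned test trials per infant (total planned trials
#'   are `d + n_test_trials`).
#' @param delta shared peak trial for the quadratic generating structure.
#' @param seed integer seed recorded in the dataset metadata.
#' @return an object of class `lt_generator_config`.
#' @export
generator_config <- function(cell_sizes = study_cell_sizes(),
                             family = "G", structure = "T",
                             mu_alpha_b = log(c(luminance = 3.7, color = 5,
                                                orientation = 5) / 2.1) -
                               log(0.93) - 0.0655,
                             mu_alpha_c = c("4M" = -0.1, "7M" = 0, "10M" = 0.1),
                             mu_beta_b = c(luminance = log(0.93),
                                           color = log(0.93),
                                           orientation = log(0.93)),
                             mu_beta_c = c("4M" = 0.005, "7M" = -0.005,
                                           "10M" = 0),
                             mu_gamma_b = c(luminance = 0.35, color = 0.25,
                                            orientation = -0.05),
                             mu_gamma_c = c("4M" = 0, "7M" = 0, "10M" = 0),
                             mu_gamma_d = c("1" = -0.096, "3" = -0.096,
                                            "5" = 0.096, "7" = 0.096),
                             scale_alpha = 0.3, scale_beta = 0.03,
                             scale_gamma = 0.15,
                             sigma_log_mean = log(2.1), sigma_log_sd = 0.2,
                             dropout_hazard = 0.029, n_test_trials = 3L,
                             delta = 1, seed = 1L) {
  stopifnot(is.data.frame(cell_sizes),
            all(c("contrast", "cohort", "n_hab_trials", "n") %in%
                  names(cell_sizes)))
  if (any(cell_sizes$n < 0) || any(cell_sizes$n != round(cell_sizes$n)))
    stop("cell sizes must be non-negative integers", call. = FALSE)
  if (sum(cell_sizes$n) == 0) stop("empty design", call. = FALSE)
  for (s in c(scale_alpha, scale_beta, scale_gamma, sigma_log_sd))
    if (s < 0) stop("population scales must be non-negative", call. = FALSE)
  if (dropout_hazard < 0 || dropout_hazard >= 1)
    stop("`dropout_hazard` must be in [0, 1)", call. = FALSE)
  cfg <- list(cell_sizes = cell_sizes, family = match_family(family),
              structure = match_structure(structure),
              mu_alpha_b = mu_alpha_b, mu_alpha_c = mu_alpha_c,
              mu_beta_b = mu_beta_b, mu_beta_c = mu_beta_c,
              mu_gamma_b = mu_gamma_b, mu_gamma_c = mu_gamma_c,
              mu_gamma_d = mu_gamma_d,
              scale_alpha = scale_alpha, scale_beta = scale_beta,
              scale_gamma = scale_gamma,
              sigma_log_mean = sigma_log_mean, sigma_log_sd = sigma_log_sd,
              dropout_hazard = dropout_hazard,
              n_test_trials = as.integer(n_test_trials),
              delta = delta, seed = as.integer(seed))
  class(cfg) <- "lt_generator_config"
  cfg
}

#' Generate a synthetic looking-time dataset
#'
#' For each infant in the configured design: draw `(alpha, beta, gamma)` from
#' the group-specific normals of the partial-pooling hierarchy, draw
#' `sigma_i` lognormally, then draw each trial's looking time from the
#' configured family and time structure. Sessions may end early through the
#' per-trial dropout hazard. The returned dataset carries the seed and full
#' configuration as attributes, and repeated calls with the same
#' configuration are identical.
#'
#' @param config an [generator_config()].
#' @return an `lt_dataset`: a data.frame with one row per trial and columns
#'   `infant_id`, `age_days`, `cohort`, `contrast`, `n_hab_trials`, `trial`,
#'   `lt_seconds`, plus attributes `config` and `seed`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "lt_generator_config"))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  cells <- cfg$cell_sizes[cfg$cell_sizes$n > 0, , drop = FALSE]
  rows <- list()
  id <- 0L
  for (k in seq_len(nrow(cells))) {
    b <- as.character(cells$contrast[k])
    co <- as.character(cells$cohort[k])
    d <- as.integer(cells$n_hab_trials[k])
    for (j in seq_len(cells$n[k])) {
      id <- id + 1L
      rng <- cohort_age_range(co)
      age <- sample(rng[1]:rng[2], 1L)
      alpha <- stats::rnorm(1, cfg$mu_alpha_b[[b]] + cfg$mu_alpha_c[[co]],
                            cfg$scale_alpha)
      beta <- stats::rnorm(1, cfg$mu_beta_b[[b]] + cfg$mu_beta_c[[co]],
                           cfg$scale_beta)
      gamma <- stats::rnorm(1, cfg$mu_gamma_b[[b]] + cfg$mu_gamma_c[[co]] +
                              cfg$mu_gamma_d[[as.character(d)]],
                            cfg$scale_gamma)
      sigma <- exp(stats::rnorm(1, cfg$sigma_log_mean, cfg$sigma_log_sd))
      n_planned <- d + cfg$n_test_trials
      y <- numeric(0)
      for (t in seq_len(n_planned)) {
        if (t > 1 && stats::runif(1) < cfg$dropout_hazard) break
        z <- switch(cfg$structure,
          trend = state_trend(alpha, beta, gamma, d, t),
          quadratic = state_quadratic(alpha, beta, gamma, cfg$delta, d, t),
          ar = state_ar(alpha, beta, gamma, d, t,
                        if (t > 1) y[t - 1], cfg$family))
        y[t] <- family_sample(cfg$family, 1L, z, sigma)
      }
      rows[[id]] <- data.frame(
        infant_id = sprintf("I%03d", id), age_days = age, cohort = co,
        contrast = b, n_hab_trials = d, trial = seq_along(y), lt_seconds = y,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  new_lt_dataset(out, config = cfg, seed = cfg$seed)
}

new_lt_dataset <- function(df, config = NULL, seed = NULL) {
  validate_lt_dataset(df)
  attr(df, "config") <- config
  attr(df, "seed") <- seed
  class(df) <- c("lt_dataset", "data.frame")
  df
}

validate_lt_dataset <- function(df) {
  need <- c("infant_id", "age_days", "cohort", "contrast", "n_hab_trials",
            "trial", "lt_seconds")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("dataset is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(df$lt_seconds) | df$lt_seconds <= 0)
  if (length(bad))
    stop("non-positive or non-finite lt_seconds in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  for (i in split(seq_len(nrow(df)), df$infant_id)) {
    tt <- df$trial[i]
    if (!identical(as.integer(tt[order(tt)]), seq_along(tt)))
      stop("trial indices for infant ", df$infant_id[i[1]],
           " are not consecutive from 1", call. = FALSE)
  }
  chk <- assign_cohort(df$age_days)
  off <- which(as.character(chk) != as.character(df$cohort))
  if (length(off))
    stop("cohort label inconsistent with age_days in row(s) ",
         paste(utils::head(off, 5), collapse = ", "), call. = FALSE)
  invisible(df)
}

#' @export
print.lt_dataset <- function(x, ...) {
  n_inf <- length(unique(x$infant_id))
  cat("<lt_dataset>", n_inf, "infants,", nrow(x), "trials\n")
  NextMethod()
}

# per-infant view used by the fitting code: list of (id, b, c, d, y, age)
dataset_infants <- function(data) {
  stopifnot(is.data.frame(data))
  ids <- unique(data$infant_id)
  lapply(ids, function(id) {
    rows <- data[data$infant_id == id, , drop = FALSE]
    rows <- rows[order(rows$trial), , drop = FALSE]
    list(id = id, contrast = as.character(rows$contrast[1]),
         cohort = as.character(rows$cohort[1]),
         d = as.integer(rows$n_hab_trials[1]), age_days = rows$age_days[1],
         t = as.integer(rows$trial), y = rows$lt_seconds)
  })
}

#' Apply the minimum-test-trials exclusion rule
#'
#' Removes infants who viewed fewer than `min_test_trials` test trials
#' (trials after trial `d`), the study's session-level exclusion rule.
#'
#' @param data an `lt_dataset`.
#' @param min_test_trials minimum number of test trials (default 3).
#' @return list with elements `data` (the filtered dataset) and `report`
#'   (excluded ids, counts, and the exclusion rate in percent).
#' @export
apply_exclusion <- function(data, min_test_trials = 3L) {
  infants <- dataset_infants(data)
  n_test <- vapply(infants, function(i) sum(i$t > i$d), integer(1))
  ids <- vapply(infants, `[[`, character(1), "id")
  drop_ids <- ids[n_test < min_test_trials]
  keep <- !(data$infant_id %in% drop_ids)
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- attr(data, "config")
  attr(out, "seed") <- attr(data, "seed")
  class(out) <- class(data)
  list(data = out,
       report = list(excluded_ids = drop_ids,
                     n_before = length(ids),
                     n_after = length(ids) - length(drop_ids),
                     exclusion_rate = 100 * length(drop_ids) / length(ids)))
}
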