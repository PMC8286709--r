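test_that("sampler configurations implement the retained-draw arithmetic", {
  expect_equal(retained_draws(sampler_config("full")), 2400)
  expect_equal(retained_draws(sampler_config("test")), 4000)
  expect_error(sampler_config(iterations = 100, warmup = 200), "warmup")
  cfg <- sampler_config(chains = 3, iterations = 500, warmup = 200, thin = 7)
  expect_equal(retained_draws(cfg), 3 * ceiling(300 / 7))
})

test_that("split R-hat separates converged from non-converged chains", {
  set.seed(1)
  chains <- replicate(6, rnorm(1000), simplify = FALSE)
  expect_lt(rhat(chains), 1.01)
  # two chains centered 10 apart: direct evaluation of the between/within
  # formula gives a large value
  apart <- list(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(rhat(apart), 3)
  # a strongly trending chain is flagged through its half-means
  trend <- list(seq(0, 1, length.out = 500) + rnorm(500, sd = 0.01),
                seq(0, 1, length.out = 500) + rnorm(500, sd = 0.01))
  expect_gt(rhat(trend), 1.1)
  expect_warning(out <- rhat(list(rep(1, 10), rep(1, 10))), "zero")
  expect_true(is.na(out))
  expect_error(rhat(list(rnorm(10))), "2 chains")
  expect_error(rhat(list(rnorm(3), rnorm(3))), "4 draws")
})

test_that("posterior summaries are empirical quantiles with nested intervals", {
  spec <- model_spec("L", "T", "none")
  post <- constant_posterior(c(alpha = 3.2), spec)
  s <- posterior_summary(post, "alpha")
  expect_true(all(s == 3.2))
  # draws 1..100: type-7 median 50.5
  draws <- matrix(1:100, ncol = 1, dimnames = list(NULL, "x"))
  post2 <- suppressWarnings(
    lookhab:::new_lt_posterior(draws, rep(1:2, each = 50), spec,
                               sampler_config(chains = 2, iterations = 100,
                                              warmup = 50)))
  s2 <- posterior_summary(post2, "x")
  expect_equal(unname(s2[["50%"]]), 50.5)
  expect_lte(s2[["2.5%"]], s2[["25%"]])
  expect_gte(s2[["97.5%"]], s2[["75%"]])
  expect_error(posterior_summary(post, "nope"), "unknown variable")
})

test_that("no-pooling fits recover near-noiseless generating parameters", {
  spec <- model_spec("L", "T", "none")
  gen <- c(alpha = 1.5, beta = -0.08, gamma = 0.3)
  set.seed(30)
  y <- exp(state_trend(gen[1], gen[2], gen[3], 5, 1:8) +
             0.003 * rnorm(8, 0, 1))
  fit <- fit_no_pooling(spec, y, d = 5, sampler_config(seed = 3))
  med <- apply(fit$draws, 2, median)
  expect_lt(abs(med[["alpha"]] - gen[["alpha"]]), 0.02)
  expect_lt(abs(med[["beta"]] - gen[["beta"]]), 0.01)
  expect_lt(abs(med[["gamma"]] - gen[["gamma"]]), 0.02)
  # and the medians sit on the maximum-likelihood solution (oracle)
  nll <- function(p) -infant_loglik(spec, list(alpha = p[1], beta = p[2],
                                               gamma = p[3],
                                               sigma = exp(p[4])), y, 5)
  ml <- optim(c(1.5, -0.08, 0.3, log(0.003)), nll, method = "BFGS")$par
  expect_lt(max(abs(med[c("alpha", "beta", "gamma")] - ml[1:3])), 0.005)
  expect_true(all(c("alpha", "beta", "gamma", "sigma") %in%
                    colnames(fit$draws)))
  # identical infants under the same seed give identical posteriors
  fit2 <- fit_no_pooling(spec, y, d = 5, sampler_config(seed = 3))
  expect_identical(fit$draws, fit2$draws)
  expect_error(fit_no_pooling(spec, y[1:3], d = 5, light_config(1)),
               "at least 4")
})

test_that("retained draw counts of real fits honor the configuration", {
  y <- lt_sample("G", 1.2, 2, 8, seed = 2)
  cfg <- sampler_config(chains = 3, iterations = 300, warmup = 150, thin = 5,
                        seed = 1)
  fit <- fit_no_pooling(model_spec("G", "T", "none"), y, 5, cfg)
  expect_equal(nrow(fit$draws), retained_draws(cfg))
  expect_equal(tabulate(fit$chain), rep(30, 3))
  expect_true(all(is.finite(fit$draws)))
  expect_true(all(fit$draws[, "sigma"] > 0))
})

test_that("partial pooling shrinks infant estimates toward the group", {
  # identical infants with modest noise: infant-level medians spread less
  # under partial pooling than under separate fits
  set.seed(10)
  cells <- study_cell_sizes()
  cells$n <- ifelse(cells$contrast == "color" & cells$cohort == "7M" &
                      cells$n_hab_trials == 3, 8L, 0L)
  cfg <- generator_config(cell_sizes = cells, family = "L",
                          scale_alpha = 0, scale_beta = 0, scale_gamma = 0,
                          sigma_log_mean = log(0.3), sigma_log_sd = 0,
                          dropout_hazard = 0, seed = 6)
  data <- generate_dataset(cfg)
  spec_p <- model_spec("L", "T", "partial")
  spec_n <- model_spec("L", "T", "none")
  fit_p <- fit_partial_pooling(spec_p, data, light_config(2))
  fit_n <- fit_dataset(spec_n, data, light_config(2))
  mp <- lookhab:::median_infant_params(fit_p)
  mn <- lookhab:::median_infant_params(fit_n)
  spread <- function(x) max(abs(x - median(x)))
  expect_lt(spread(mp$alpha), spread(mn$alpha))
  expect_lt(spread(mp$beta), spread(mn$beta))
})

test_that("huge fixed population scales reproduce the no-pooling posterior", {
  set.seed(11)
  cells <- study_cell_sizes()
  cells$n <- ifelse(cells$contrast == "color" & cells$cohort == "7M" &
                      cells$n_hab_trials == 5, 4L, 0L)
  cfg <- generator_config(cell_sizes = cells, family = "L",
                          sigma_log_mean = log(0.4), dropout_hazard = 0,
                          seed = 14)
  data <- generate_dataset(cfg)
  fit_p <- fit_partial_pooling(model_spec("L", "T", "partial"), data,
                               sampler_config(seed = 3),
                               fixed_scales = c(10, 10, 10),
                               pool_sigma = FALSE)
  fit_n <- fit_dataset(model_spec("L", "T", "none"), data,
                       sampler_config(seed = 3))
  mp <- lookhab:::median_infant_params(fit_p)
  mn <- lookhab:::median_infant_params(fit_n)
  # agreement within half a posterior standard deviation per infant
  for (i in seq_len(nrow(mp))) {
    id <- mp$infant_id[i]
    sd_a <- sd(fit_n[[id]]$draws[, "alpha"])
    expect_lt(abs(mp$alpha[i] - mn$alpha[mn$infant_id == id]), 0.5 * sd_a)
  }
})

test_that("posterior serialization round-trips draws and diagnostics", {
  y <- lt_sample("G", 1.2, 2, 8, seed = 2)
  fit <- fit_no_pooling(model_spec("G", "T", "none"), y, 5, light_config(1))
  path <- tempfile(fileext = ".csv")
  write_posterior(fit, path)
  long <- read.csv(path)
  expect_setequal(unique(long$variable), colnames(fit$draws))
  expect_equal(nrow(long), nrow(fit$draws) * ncol(fit$draws))
  back <- matrix(long$value[long$variable == "alpha"], ncol = 1)
  expect_equal(as.vector(back), unname(fit$draws[, "alpha"]))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$model, "GTN")
  expect_equal(meta$converged, fit$converged)
  unlink(c(path, paste0(path, ".json")))
})
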