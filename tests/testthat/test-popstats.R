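test_that("the omnibus ANOVA reproduces hand-computed F statistics", {
  # one factor, groups {1,2,3} and {4,5,6}: F = 13.5 on (1, 4) df
  params <- data.frame(contrast = rep(c("luminance", "color"), each = 3),
                       cohort = "7M", n_hab_trials = 3,
                       alpha = c(1, 2, 3, 4, 5, 6))
  tab <- anova_table(params, design = list(alpha = "S"))
  expect_equal(tab$F, 13.5)
  expect_equal(tab$df1, 1)
  expect_equal(tab$df2, 4)
  expect_equal(tab$p, 1 - pf(13.5, 1, 4))
  expect_true(tab$significant)
  # translation invariance
  params2 <- params
  params2$alpha <- params2$alpha + 100
  expect_equal(anova_table(params2, design = list(alpha = "S"))$F, 13.5)
  # the dishabituation parameter gets the full seven-term layout
  set.seed(3)
  big <- expand.grid(contrast = c("luminance", "color", "orientation"),
                     cohort = c("4M", "7M", "10M"),
                     n_hab_trials = c(1, 3, 5, 7), rep = 1:3)
  big$alpha <- rnorm(nrow(big))
  big$beta <- rnorm(nrow(big))
  big$gamma <- rnorm(nrow(big))
  full <- anova_table(big)
  expect_setequal(full$term[full$parameter == "gamma"],
                  c("S", "A", "S:A", "T", "T:S", "T:A", "T:S:A"))
  expect_setequal(full$term[full$parameter == "alpha"], c("S", "A", "S:A"))
  # non-converged rows are dropped before testing
  big2 <- big
  big2$converged <- TRUE
  big2$converged[1] <- FALSE
  expect_s3_class(anova_table(big2), "lt_anova_table")
})

test_that("ANOVA F tests agree with a permutation oracle on clear effects", {
  set.seed(8)
  agree <- 0
  cases <- 6
  for (k in seq_len(cases)) {
    dsg <- expand.grid(contrast = c("luminance", "color"),
                       cohort = c("4M", "7M"), rep = 1:15)
    # clearly separated main effects on both factors
    dsg$gamma <- 1.2 * (dsg$contrast == "color") +
      0.9 * (dsg$cohort == "7M") + rnorm(nrow(dsg), sd = 0.5)
    dsg$n_hab_trials <- 3
    tab <- anova_table(dsg, design = list(gamma = c("S", "A")))
    p_perm <- perm_anova_oracle(dsg$gamma, dsg$contrast, dsg$cohort)
    dec_f <- tab$p[match(c("S", "A"), tab$term)] < 0.05
    dec_p <- p_perm < 0.05
    agree <- agree + sum(dec_f == dec_p)
  }
  expect_gte(agree / (2 * cases), 0.95)
})

test_that("pure-noise responses give F statistics near one", {
  set.seed(21)
  dsg <- expand.grid(contrast = c("luminance", "color", "orientation"),
                     cohort = c("4M", "7M", "10M"), rep = 1:34)
  dsg$n_hab_trials <- 3
  f_vals <- replicate(20, {
    dsg$alpha <- rnorm(nrow(dsg))
    anova_table(dsg, design = list(alpha = c("S", "A")))$F
  })
  expect_equal(mean(f_vals), 1, tolerance = 0.25)
})

test_that("the parameter-correlation table computes the six Pearson pairs", {
  set.seed(5)
  n <- 50
  params <- data.frame(alpha = rnorm(n), beta = rnorm(n), gamma = rnorm(n))
  params$sigma <- 2 * params$alpha + 1 # exact linear relation
  ct <- correlation_table(params)
  expect_named(ct, c("r_alpha_sigma", "r_beta_sigma", "r_gamma_sigma",
                     "r_alpha_beta", "r_alpha_gamma", "r_beta_gamma"))
  expect_equal(unname(ct["r_alpha_sigma"]), 1)
  expect_equal(unname(ct["r_alpha_beta"]), cor(params$alpha, params$beta))
  # sign flip of one parameter negates its three correlations
  flip <- params
  flip$gamma <- -flip$gamma
  cf <- correlation_table(flip)
  expect_equal(unname(cf[c("r_gamma_sigma", "r_alpha_gamma",
                           "r_beta_gamma")]),
               unname(-ct[c("r_gamma_sigma", "r_alpha_gamma",
                            "r_beta_gamma")]))
  expect_equal(unname(cf["r_alpha_beta"]), unname(ct["r_alpha_beta"]))
  # independence: with n = 300 all |r| stay inside the Fisher null band in
  # the typical case
  set.seed(11)
  ind <- data.frame(alpha = rnorm(300), beta = rnorm(300),
                    gamma = rnorm(300), sigma = rnorm(300))
  ci <- correlation_table(ind)
  expect_true(all(abs(ci) < tanh(3.5 / sqrt(297))))
  # degenerate input: one warning per undefined pair
  params$sigma <- 1
  w <- capture_warnings(cz <- correlation_table(params))
  expect_length(w, 3)
  expect_match(w, "zero variance", all = TRUE)
  expect_true(is.na(cz["r_alpha_sigma"]))
  expect_error(correlation_table(params[1:3, ]), "at least 4")
})

test_that("main-effect summaries percent-transform the multiplicative scales", {
  spec <- model_spec("L", "T", "partial")
  vals <- c()
  for (b in c("luminance", "color", "orientation")) {
    vals[paste0("mu_alpha_b[", b, "]")] <- 1.4
    vals[paste0("mu_beta_b[", b, "]")] <- log(0.93)
    vals[paste0("mu_gamma_b[", b, "]")] <- 0.1
  }
  for (cc in c("4M", "7M", "10M")) {
    vals[paste0("mu_alpha_c[", cc, "]")] <- 0
    vals[paste0("mu_beta_c[", cc, "]")] <- 0
    vals[paste0("mu_gamma_c[", cc, "]")] <- 0
  }
  for (dd in c(1, 3, 5, 7)) vals[paste0("mu_gamma_d[", dd, "]")] <- 0.1
  post <- constant_posterior(vals, spec)
  s <- main_effects_summary(post)
  slope <- s[s$parameter == "beta" & s$group == "luminance", ]
  expect_equal(slope$unit, "percent")
  expect_equal(round(slope[["50%"]], 1), -7.0)
  offset <- s[s$parameter == "alpha" & s$group == "7M", ]
  expect_equal(offset$unit, "log-seconds")
  expect_equal(offset[["50%"]], 1.4)
  # the additive normal family reports seconds, untransformed
  post_n <- constant_posterior(vals, model_spec("N", "T", "partial"))
  sn <- main_effects_summary(post_n)
  expect_true(all(sn$unit == "seconds"))
  expect_equal(sn[sn$parameter == "beta" & sn$group == "luminance", "50%"],
               log(0.93))
  # monotone transform commutes with quantiles
  # exact for order statistics; interpolated quantiles agree to first order
  x <- rnorm(500, -0.07, 0.03)
  expect_equal(quantile(percent_change(x), c(0.25, 0.75)),
               percent_change(quantile(x, c(0.25, 0.75))),
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("the early-vs-late dishabituation contrast is percent-scaled", {
  spec <- model_spec("L", "T", "partial", gamma_effects = "interaction")
  cells <- as.vector(t(outer(c("luminance", "color", "orientation"),
                             c(1, 3, 5, 7), paste, sep = ",")))
  base <- setNames(rep(0, 12), paste0("mu_gamma_bd[", cells, "]"))
  # all cells equal: null contrast
  expect_equal(unname(dishabituation_contrast(
    constant_posterior(base + 0.3, spec))[["50%"]]), 0)
  # late cells at 0.2: contrast 0.2 on the latent scale = 22.1 percent
  late <- base
  late[paste0("mu_gamma_bd[", c("luminance,5", "luminance,7", "color,5",
                                "color,7"), "]")] <- 0.2
  cst <- dishabituation_contrast(constant_posterior(late, spec))
  expect_equal(round(unname(cst[["50%"]]), 1), 22.1)
  # swapping early and late cells negates the latent contrast
  early <- base
  early[paste0("mu_gamma_bd[", c("luminance,1", "luminance,3", "color,1",
                                 "color,3"), "]")] <- 0.2
  cste <- dishabituation_contrast(constant_posterior(early, spec))
  expect_equal(log(1 + cste[["50%"]] / 100), -log(1 + cst[["50%"]] / 100),
               tolerance = 1e-12, ignore_attr = TRUE)
  # main-effects posteriors are rejected
  expect_error(dishabituation_contrast(
    constant_posterior(base, model_spec("L", "T", "partial"))), "interaction")
})

test_that("habituation-criterion trial counts follow the multiplicative decay", {
  expect_equal(trials_to_criterion(0.07, 0.5), 10L)
  expect_equal(trials_to_criterion(0.5, 0.5), 1L)
  # brute-force oracle over t
  scan <- function(rho, crit) {
    t <- 1
    while ((1 - rho)^t > crit) t <- t + 1
    t
  }
  expect_equal(trials_to_criterion(0.07, 0.3), scan(0.07, 0.3))
  expect_equal(trials_to_criterion(0.07, 0.3), 17L)
  # monotone: non-increasing in the decrease, non-decreasing in the criterion
  expect_true(all(diff(sapply(c(0.03, 0.07, 0.15, 0.4),
                              trials_to_criterion, criterion = 0.5)) <= 0))
  expect_true(all(diff(sapply(c(0.2, 0.4, 0.6, 0.8), function(cr)
    trials_to_criterion(0.07, cr))) <= 0))
  expect_error(trials_to_criterion(0, 0.5), "strictly in")
  expect_error(trials_to_criterion(0.07, 1), "strictly in")
})

test_that("the running-average criterion needs more trials than the plain one", {
  # brute-force oracle under LT_t = (1 - rho)^(t - 1)
  oracle <- function(rho, crit, w) {
    lt <- (1 - rho)^(0:99)
    first <- mean(lt[1:w])
    for (t in w:100)
      if (mean(lt[(t - w + 1):t]) <= crit * first) return(t)
  }
  expect_equal(running_average_criterion_trials(0.07, 0.5, 3),
               oracle(0.07, 0.5, 3))
  expect_equal(running_average_criterion_trials(0.07, 0.5, 3), 13L)
  expect_gte(running_average_criterion_trials(0.07, 0.5, 3), 12L)
  # window 1 reduces to the plain criterion shifted by the decay convention
  expect_equal(running_average_criterion_trials(0.07, 0.5, 1),
               trials_to_criterion(0.07, 0.5) + 1L)
  # a lax criterion is met as soon as the window slides once
  expect_equal(running_average_criterion_trials(0.07, 0.999, 3), 4L)
})

test_that("Fisher confidence half-widths match the printed interval width", {
  hw <- fisher_ci_halfwidth(301, 0)
  expect_equal(round(unname(hw["upper"]), 3), 0.113)
  expect_equal(unname(hw["lower"]), unname(hw["upper"])) # symmetric at r = 0
  expect_equal(unname(fisher_ci_halfwidth(103, 0)["upper"]), tanh(0.196),
               tolerance = 1e-4)
  big <- fisher_ci_halfwidth(1e6, 0.3)
  expect_lt(max(big), 0.01)
  r6 <- fisher_ci_halfwidth(301, 0.6)
  expect_lt(r6[["upper"]], r6[["lower"]]) # interval shrinks toward +1
  expect_true(all(fisher_ci_halfwidth(50, -0.4) > 0))
  expect_error(fisher_ci_halfwidth(3, 0), "at least 4")
  expect_error(fisher_ci_halfwidth(100, 1), "\\|r\\|")
})
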