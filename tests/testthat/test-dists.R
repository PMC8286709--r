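test_that("log-densities reduce to known special cases", {
  # shape-1 gamma and Weibull are the unit-rate exponential
  expect_equal(lt_logpdf("G", 1, 0, 1), -1)
  expect_equal(lt_logpdf("W", 1, 0, 1), -1)
  # truncated normal at z = 0 is the half-normal
  expect_equal(exp(lt_logpdf("N", 0.5, 0, 1)), 2 * dnorm(0.5),
               tolerance = 1e-12)
  # lognormal agrees with dlnorm
  expect_equal(lt_logpdf("L", 2.3, 0.4, 0.7),
               dlnorm(2.3, 0.4, 0.7, log = TRUE))
  expect_error(lt_logpdf("G", -1, 0, 1), "positive")
  expect_error(lt_logpdf("G", 1, 0, 0), "positive")
  expect_error(lt_logpdf("G", 1, Inf, 1), "finite")
  expect_error(lt_logpdf("Z", 1, 0, 1), "unknown family")
})

test_that("every family's density integrates to one on the positive reals", {
  for (fam in lt_families()) {
    for (z in c(-0.5, 0.5, 1.5)) {
      for (sigma in c(0.5, 1, 2.5)) {
        total <- integrate(function(y) exp(lt_logpdf(fam, y, z, sigma)),
                           0, Inf, rel.tol = 1e-10)$value
        expect_equal(total, 1, tolerance = 1e-6,
                     label = sprintf("integral %s z=%g s=%g", fam, z, sigma))
      }
    }
  }
})

test_that("seeded sampling is reproducible and matches the density", {
  expect_identical(lt_sample("G", 0.3, 1.4, 50, seed = 9),
                   lt_sample("G", 0.3, 1.4, 50, seed = 9))
  # empirical CDF of 1e5 draws vs the implied CDF, per family
  cdf <- list(
    N = function(q, z, s) (pnorm(q, z, s) - pnorm(0, z, s)) / pnorm(z / s),
    E = function(q, z, s) {
      m <- exp(z)
      (pnorm(q, m, s) - pnorm(0, m, s)) / pnorm(m / s)
    },
    L = function(q, z, s) plnorm(q, z, s),
    W = function(q, z, s) pweibull(q, shape = s, scale = exp(z)),
    G = function(q, z, s) pgamma(q, shape = s, scale = exp(z))
  )
  pars <- list(N = c(2, 1), E = c(0.9, 1), L = c(0.8, 0.6), W = c(1, 1.6),
               G = c(0.4, 2.1))
  for (fam in lt_families()) {
    z <- pars[[fam]][1]; s <- pars[[fam]][2]
    y <- lt_sample(fam, z, s, 1e5, seed = 31)
    expect_true(all(y > 0))
    ks <- max(abs(ecdf(y)(y) - cdf[[fam]](y, z, s)))
    expect_lt(ks, 0.01)
  }
  # closed-form gamma mean within 3 Monte-Carlo standard errors
  y <- lt_sample("G", 0, 2, 1e5, seed = 7)
  se <- sqrt(2 * exp(0)^2 / 1e5) # var = shape * scale^2
  expect_lt(abs(mean(y) - 2), 3 * se)
  # degenerate lognormal limit
  expect_equal(lt_sample("L", 0, 1e-12, 10, seed = 1), rep(1, 10),
               tolerance = 1e-9)
  expect_true(all(lt_sample("N", 3, 0.1, 100, seed = 2) > 0))
})

test_that("log geometric mean is linear in z with the known sigma offsets", {
  expect_equal(lt_log_geometric_mean("L", 1.2, 0.7), 1.2)
  # independent oracle: numerical integration of log(y) against the density
  elog <- function(fam, z, s)
    integrate(function(y) log(y) * exp(lt_logpdf(fam, y, z, s)), 0, Inf,
              rel.tol = 1e-10)$value
  expect_equal(lt_log_geometric_mean("G", 0, 2), elog("G", 0, 2),
               tolerance = 1e-6)
  expect_equal(lt_log_geometric_mean("G", 0, 2), digamma(2),
               tolerance = 1e-12)
  expect_equal(lt_log_geometric_mean("W", 0.5, 2), elog("W", 0.5, 2),
               tolerance = 1e-6)
  expect_error(lt_log_geometric_mean("N", 0, 1), "L, W, G")
  expect_error(lt_log_geometric_mean("E", 0, 1), "L, W, G")
  # d/dz E[log Y] = 1 for the log-link families (finite differences)
  h <- 1e-5
  for (fam in c("L", "W", "G")) {
    for (s in c(0.6, 1.7)) {
      d1 <- (lt_log_geometric_mean(fam, 0.4 + h, s) -
               lt_log_geometric_mean(fam, 0.4 - h, s)) / (2 * h)
      expect_equal(d1, 1, tolerance = 1e-6)
    }
  }
})

test_that("Fisher information has the closed-form entries", {
  expect_equal(unname(lt_fisher_information("L", sigma = 1)),
               diag(c(1, 2)))
  g <- lt_fisher_information("G", sigma = 2)
  expect_equal(unname(g), matrix(c(2, 1, 1, trigamma(2)), 2, 2),
               tolerance = 1e-12)
  eg <- -digamma(1)
  w <- lt_fisher_information("W", sigma = 1)
  expect_equal(w[1, 1], 1)
  expect_equal(w[1, 2], -(1 - eg), tolerance = 1e-12)
  expect_equal(w[2, 2], pi^2 / 6 + (1 - eg)^2, tolerance = 1e-12)
  # symmetric positive definite across families
  for (fam in lt_families()) {
    fi <- lt_fisher_information(fam, z = 1, sigma = 1.3)
    expect_equal(fi, t(fi))
    expect_true(all(eigen(fi)$values > 0))
  }
})

test_that("parameter correlation follows the inverse information", {
  expect_equal(round(lt_parameter_correlation("G", 2.1), 2), 0.89)
  expect_equal(round(lt_parameter_correlation("W", 0.7), 2), 0.31)
  expect_equal(lt_parameter_correlation("W", 4), lt_parameter_correlation("W", 0.2))
  expect_equal(lt_parameter_correlation("L", 0.5), 0)
  expect_equal(lt_parameter_correlation("N", 2), 0)
  expect_equal(lt_parameter_correlation("E", 2), 0)
  # consistency with the inverse Fisher information, all families
  for (fam in lt_families()) {
    fi <- lt_fisher_information(fam, z = 0.3, sigma = 1.8)
    v <- solve(fi)
    r_inv <- abs(v[1, 2] / sqrt(v[1, 1] * v[2, 2]))
    expect_equal(lt_parameter_correlation(fam, 1.8), r_inv,
                 tolerance = 5e-4)
  }
  # gamma correlation is strictly increasing with the known limits
  ss <- c(1e-4, 0.01, 0.1, 1, 10, 100, 1e4)
  rr <- lt_parameter_correlation("G", ss)
  expect_true(all(diff(rr) > 0))
  expect_lt(rr[1], 0.05)
  expect_gt(rr[length(rr)], 0.95)
  expect_error(lt_parameter_correlation("G", -1), "positive")
})

test_that("replicated maximum-likelihood fits reproduce the asymptotic correlation", {
  # Monte-Carlo oracle for the analytic claim: the empirical correlation of
  # (z-hat, sigma-hat) over replicated samples matches the inverse-information
  # correlation
  set.seed(42)
  for (fam in c("W", "G")) {
    sigma0 <- if (fam == "W") 1.6 else 2.1
    est <- t(replicate(500, ml_fit_family(fam, lt_sample(fam, 0.5, sigma0,
                                                         200))))
    r_emp <- cor(est[, "z"], est[, "sigma"])
    expect_equal(abs(r_emp), lt_parameter_correlation(fam, sigma0),
                 tolerance = 0.08)
    # sign of the inverse-information off-diagonal: positive for Weibull,
    # negative for gamma (shape and scale trade off against a fixed mean)
    if (fam == "W") expect_gt(r_emp, 0) else expect_lt(r_emp, 0)
  }
})

test_that("percent transform is exact and invertible", {
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(log(2)), 100)
  expect_equal(round(percent_change(-0.07257), 1), -7.0)
  x <- c(-0.3, 0, 0.15, 2)
  expect_equal(percent_change_inverse(percent_change(x)), x)
  expect_true(all(diff(percent_change(seq(-1, 1, 0.1))) > 0))
  expect_error(percent_change(Inf), "finite")
  expect_error(percent_change_inverse(-100), "greater than -100")
})
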