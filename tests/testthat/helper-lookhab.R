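# shared fixtures and independent oracles, built in code at test time

# light sampler configuration for the many small fits in the suite
light_config <- function(seed = 1L) {
  sampler_config(chains = 2L, iterations = 800L, warmup = 400L, seed = seed)
}

# study-shaped design scaled down to about 60 infants
design60 <- function() {
  cells <- study_cell_sizes()
  cells$n <- pmax(1L, round(cells$n * 60 / 301))
  cells
}

# a small balanced design (used where cell sizes are irrelevant)
design_small <- function(n_per_cell = 2L, d_levels = c(3L, 5L)) {
  cells <- study_cell_sizes()
  cells$n <- ifelse(cells$n_hab_trials %in% d_levels, n_per_cell, 0L)
  cells
}

# hand-built degenerate posterior over arbitrary named variables
constant_posterior <- function(values, spec, n = 8L, chains = 2L) {
  draws <- matrix(rep(unlist(values), each = n * chains),
                  nrow = n * chains,
                  dimnames = list(NULL, names(values)))
  post <- suppressWarnings(
    lookhab:::new_lt_posterior(draws, rep(seq_len(chains), each = n), spec,
                               sampler_config(chains = chains,
                                              iterations = 2L * n,
                                              warmup = n)))
  post$converged <- TRUE # degenerate draws are converged by construction
  post
}

# displayed population-mean truths under the main-effects display convention
# (group mean plus the average of the other factor's means)
display_truth <- function(cfg) {
  out <- c()
  for (par in c("alpha", "beta", "gamma")) {
    mb <- unlist(cfg[[paste0("mu_", par, "_b")]])
    mc <- unlist(cfg[[paste0("mu_", par, "_c")]])
    for (b in names(mb))
      out[paste0(par, ".contrast.", b)] <- mb[[b]] + mean(mc)
    for (cc in names(mc))
      out[paste0(par, ".cohort.", cc)] <- mc[[cc]] + mean(mb)
    if (par == "gamma")
      for (dd in names(cfg$mu_gamma_d))
        out[paste0(par, ".d.", dd)] <-
          cfg$mu_gamma_d[[dd]] + mean(mb) + mean(mc)
  }
  out
}

# displayed population-mean posterior draws matching display_truth()
display_draws <- function(fit) {
  d <- fit$draws
  bl <- c("luminance", "color", "orientation")
  cl <- c("4M", "7M", "10M")
  out <- list()
  for (par in c("alpha", "beta", "gamma")) {
    bn <- paste0("mu_", par, "_b[", bl, "]")
    cn <- paste0("mu_", par, "_c[", cl, "]")
    for (b in bl)
      out[[paste0(par, ".contrast.", b)]] <-
        d[, paste0("mu_", par, "_b[", b, "]")] + rowMeans(d[, cn])
    for (cc in cl)
      out[[paste0(par, ".cohort.", cc)]] <-
        d[, paste0("mu_", par, "_c[", cc, "]")] + rowMeans(d[, bn])
    if (par == "gamma")
      for (dd in c(1, 3, 5, 7))
        out[[paste0(par, ".d.", dd)]] <-
          d[, paste0("mu_gamma_d[", dd, "]")] + rowMeans(d[, bn]) +
          rowMeans(d[, cn])
  }
  out
}

# cache for the replicated hierarchical-recovery experiment shared by the
# coverage and correlation-null acceptance checks
.lookhab_cache <- new.env(parent = emptyenv())

recovery_experiment <- function(n_reps = 20L) {
  key <- paste0("recovery", n_reps)
  if (!is.null(.lookhab_cache[[key]])) return(.lookhab_cache[[key]])
  spec <- model_spec("G", "T", "partial")
  cells <- design60()
  reps <- lapply(seq_len(n_reps), function(r) {
    cfg <- generator_config(cell_sizes = cells, seed = 100L + r)
    data <- apply_exclusion(generate_dataset(cfg))$data
    fit <- fit_partial_pooling(spec, data,
                               sampler_config(seed = 500L + r))
    truth <- display_truth(cfg)
    dr <- display_draws(fit)
    covered <- vapply(names(truth), function(nm) {
      ci <- stats::quantile(dr[[nm]], c(0.025, 0.975))
      truth[[nm]] >= ci[1] && truth[[nm]] <= ci[2]
    }, logical(1))
    list(fit = fit, covered = covered,
         params = lookhab:::median_infant_params(fit))
  })
  .lookhab_cache[[key]] <- reps
  reps
}

# maximum-likelihood fit of one family's (z, sigma) by direct optimization
ml_fit_family <- function(family, y) {
  nll <- function(p) {
    v <- suppressWarnings(-sum(lt_logpdf(family, y, p[1], exp(p[2]))))
    if (!is.finite(v)) 1e10 else v
  }
  start <- c(mean(log(y)), 0)
  o <- stats::optim(start, nll, method = "BFGS")
  c(z = o$par[1], sigma = exp(o$par[2]))
}

# permutation F-test oracle for a two-factor design: term-wise restricted
# permutations (permute responses within the levels of the other factor)
perm_anova_oracle <- function(y, f1, f2, n_perm = 2000L) {
  f_stat <- function(y, fac) {
    m <- tapply(y, fac, mean)
    n <- tapply(y, fac, length)
    ssb <- sum(n * (m - mean(y))^2)
    ssw <- sum((y - m[fac])^2)
    (ssb / (length(m) - 1)) / (ssw / (length(y) - length(m)))
  }
  p_term <- function(target, strata) {
    obs <- f_stat(y, target)
    perm <- replicate(n_perm, {
      yp <- unlist(lapply(split(y, strata), sample), use.names = FALSE)
      ord <- unlist(split(seq_along(y), strata), use.names = FALSE)
      yy <- numeric(length(y))
      yy[ord] <- yp
      f_stat(yy, target)
    })
    (1 + sum(perm >= obs)) / (1 + n_perm)
  }
  c(p1 = p_term(f1, f2), p2 = p_term(f2, f1))
}
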