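# Independent oracles and small cohort builders used across the test files.
# Oracles are deliberately naive re-derivations, kept free of the package's
# own code paths.

# Naive Cox log partial likelihood for untied data (Breslow form reduces to
# the exact likelihood when no event times tie). One covariate.
naive_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

# Two-sided Fisher exact p for a 2x2 table by exhaustive hypergeometric
# enumeration: sum of P(tables) with probability <= observed (with a small
# relative tolerance, the convention R itself uses).
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random untied survival instance for oracle cross-checks.
random_surv_instance <- function(n, p = 1, event_rate = 0.7) {
  tm <- rexp(n, 0.1)
  ev <- rbinom(n, 1, event_rate)
  if (sum(ev) == 0) ev[sample.int(n, 1)] <- 1
  list(time = tm, event = ev, x = matrix(rnorm(n * p), n, p))
}

# Small cohort with a single planted gene, all nuisance covariate effects
# zero unless stated otherwise.
plain_cohort <- function(n, loghr = 0, seed = 1, n_genes = 1,
                         covariate_effects = c(mutation = 0, sex = 0,
                                               age = 0, treatment = 0),
                         ...) {
  cfg <- SimulationConfig(
    n_patients = n, n_genes = n_genes,
    planted_index = if (loghr != 0) 1L else integer(0),
    planted_loghr = if (loghr != 0) loghr else numeric(0),
    covariate_effects = covariate_effects, seed = seed, ...)
  generateCohort(cfg)
}

# Univariate per-SD Cox p-value for one gene of a cohort.
gene_univariate <- function(cohort, gene = "g0001") {
  cd <- clinicalData(cohort)
  z <- as.numeric(scale(exprsMatrix(cohort)[gene, ]))
  fit <- coxFit(cd$os_months, cd$event, z)
  w <- waldSummary(fit)
  list(fit = fit, coef = fit@coef[[1]], p = w$p[1],
       lower = w$lower[1], upper = w$upper[1])
}
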