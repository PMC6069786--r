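# Survival primitives against hand computations, brute-force oracles and
# the survival package as an independent reference.

test_that("Kaplan-Meier matches hand product-limit computations", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km@surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km@median, 2)
  expect_equal(km@n_risk, c(3, 2, 1))

  # censored exactly at an event time counts as at risk there
  km2 <- kmEstimate(c(1, 2), c(1, 0))
  expect_equal(km2@surv, 0.5)
  expect_equal(km2@median, 1)  # smallest event time with survival <= 0.5

  # all censored: survival never leaves 1, median undefined
  km3 <- kmEstimate(c(1, 2, 3), c(0, 0, 0))
  expect_length(km3@time, 0)
  expect_true(is.na(km3@median))

  # no censoring: KM equals the empirical survival function
  tm <- c(2, 5, 7, 11, 13)
  km4 <- kmEstimate(tm, rep(1, 5))
  expect_equal(km4@surv, 1 - seq_len(5) / 5)

  expect_error(kmEstimate(c(0, 1), c(1, 1)), class = "inputError")
})

test_that("log-rank matches the single-2x2 hand example and is symmetric", {
  lr <- logrankTest(c(1, 2), c(1, 0), c("A", "B"))
  expect_equal(lr@statistic, 1)       # (1 - 0.5)^2 / 0.25
  expect_equal(lr@df, 1L)
  expect_equal(lr@p, pchisq(1, 1, lower.tail = FALSE))

  set.seed(41)
  d <- random_surv_instance(30)
  g <- sample(c("x", "y"), 30, replace = TRUE)
  a <- logrankTest(d$time, d$event, g)
  b <- logrankTest(d$time, d$event, ifelse(g == "x", "y", "x"))
  expect_equal(a@statistic, b@statistic)
  expect_equal(a@p, b@p)

  expect_error(logrankTest(c(1, 2), c(1, 1), c("A", "A")),
               class = "inputError")
  expect_error(logrankTest(c(1, 2), c(0, 0), c("A", "B")),
               class = "inputError")
})

test_that("log-rank agrees with survival::survdiff on random instances", {
  skip_if_not_installed("survival")
  set.seed(7)
  for (i in 1:50) {
    n <- sample(10:30, 1)
    tm <- round(rexp(n, 0.1), sample(0:2, 1)) + 0.5   # ties sometimes
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    g <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(g)) < 2) g[1:2] <- c("A", "B")
    ref <- survival::survdiff(survival::Surv(tm, ev) ~ g)
    expect_equal(logrankTest(tm, ev, g)@statistic, ref$chisq,
                 tolerance = 1e-8)
  }
})

test_that("Cox fit maximizes the partial likelihood (brute-force oracle)", {
  # n = 6, one continuous covariate, untied times
  tm <- c(1.3, 2.1, 3.7, 4.2, 5.9, 7.4)
  ev <- c(1, 1, 0, 1, 1, 1)
  x <- c(0.2, -1.1, 0.8, 1.6, -0.4, 0.5)
  fit <- coxFit(tm, ev, x)
  oracle <- optimize(function(b) naive_partial_loglik(b, tm, ev, x),
                     c(-10, 10), maximum = TRUE)
  expect_equal(fit@coef[[1]], oracle$maximum, tolerance = 1e-3)
  expect_equal(fit@loglik, oracle$objective, tolerance = 1e-8)
  expect_true(fit@converged)
  expect_lt(max(abs(fit@score)), 1e-9)   # final gradient below tol
})

test_that("Cox fits agree with survival::coxph to 1e-6 (both tie methods)", {
  skip_if_not_installed("survival")
  set.seed(11)
  for (i in 1:50) {
    n <- sample(15:50, 1)
    p <- sample(1:3, 1)
    tm <- round(rexp(n, 0.1), sample(0:2, 1)) + 0.5
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    X <- matrix(rnorm(n * p), n, p)
    for (ties in c("efron", "breslow")) {
      mine <- coxFit(tm, ev, X, ties = ties)
      ref <- survival::coxph(survival::Surv(tm, ev) ~ X, ties = ties)
      expect_equal(unname(mine@coef), unname(coef(ref)), tolerance = 1e-6)
      expect_equal(unname(mine@se), unname(sqrt(diag(vcov(ref)))),
                   tolerance = 1e-6)
    }
  }
})

test_that("score test at zero equals the log-rank chi-square (binary, untied)", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(12:40, 1)
    tm <- rexp(n, 0.1)
    ev <- rbinom(n, 1, 0.75)
    if (sum(ev) == 0) ev[1] <- 1
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2) g[1:2] <- 0:1
    st <- coxScoreTest(tm, ev, g)
    lr <- logrankTest(tm, ev, g)
    expect_equal(st$statistic, lr@statistic, tolerance = 1e-8)
  }
})

test_that("Efron and Breslow coincide exactly without tied event times", {
  set.seed(17)
  d <- random_surv_instance(40, p = 2)
  fe <- coxFit(d$time, d$event, d$x, ties = "efron")
  fb <- coxFit(d$time, d$event, d$x, ties = "breslow")
  expect_identical(fe@coef, fb@coef)
  expect_identical(fe@loglik, fb@loglik)
})

test_that("null covariates recover coefficient near zero", {
  set.seed(19)
  n <- 600
  tm <- rexp(n, 0.1)
  ev <- rbinom(n, 1, 0.8)
  x <- rnorm(n)                       # independent of survival
  fit <- coxFit(tm, ev, x)
  expect_lt(abs(fit@coef[[1]]), 0.1)
  expect_equal(exp(fit@coef[[1]]), 1, tolerance = 0.1)
})

test_that("divergence and degenerate inputs are flagged, never silent", {
  # perfect separation: the only events are in the x = 1 arm and occur first
  tm <- c(1, 2, 3, 10, 11, 12)
  ev <- c(1, 1, 1, 0, 0, 0)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- coxFit(tm, ev, x)
  expect_false(fit@converged)
  expect_error(waldSummary(fit), class = "convergenceError")

  expect_error(coxFit(c(1, 2), c(1, 1), c(3, 3)), class = "inputError")
  expect_error(coxFit(c(1, 2), c(0, 0), c(1, 2)), class = "inputError")
})

test_that("Wald summaries follow the display conventions", {
  fit <- .CoxFit(coef = c(x1 = 0), se = c(x1 = 0.2), loglik = 0,
                 loglik0 = 0, score = 0, imat = diag(1), iter = 1L,
                 converged = TRUE, ties = "efron", n = 10L, nevent = 5L,
                 scale = "")
  w <- waldSummary(fit)
  expect_equal(w$hr, 1)
  expect_equal(w$p, 1)
  expect_equal(w$lower * w$upper, 1)  # symmetric about 1 on the log scale

  # back-solved from an HR 1.29 (1.04-1.59) display
  fit2 <- .CoxFit(coef = c(expr = 0.2546), se = c(expr = 0.1083),
                  loglik = 0, loglik0 = 0, score = 0, imat = diag(1),
                  iter = 1L, converged = TRUE, ties = "efron", n = 311L,
                  nevent = 250L, scale = "")
  w2 <- waldSummary(fit2)
  expect_equal(round(w2$hr, 2), 1.29)
  expect_equal(round(w2$lower, 2), 1.04)
  expect_equal(round(w2$upper, 2), 1.59)

  w99 <- waldSummary(fit2, level = 0.99)
  expect_lt(w99$lower, w2$lower)
  expect_gt(w99$upper, w2$upper)
})
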