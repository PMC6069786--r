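# Dichotomization, stratified KM, multivariate adjustment, subgroups,
# methylation association, cohort summaries and cross-cohort tests.

test_that("dichotomization follows the stated tie and tertile rules", {
  a <- dichotomize(c(p1 = 1, p2 = 2, p3 = 3, p4 = 4))
  expect_equal(as.character(a), c("low", "low", "high", "high"),
               ignore_attr = TRUE)

  # values tying the median go low
  b <- dichotomize(c(p1 = 5, p2 = 5, p3 = 5, p4 = 7))
  expect_equal(sum(b == "low"), 3)

  # lower tertile: floor(n/3) smallest
  v <- setNames(c(9, 1, 5, 3, 8, 2, 7, 4, 6), paste0("p", 1:9))
  d <- dichotomize(v, rule = "lower-tertile")
  expect_equal(sum(d == "low"), 3)
  expect_setequal(names(d)[d == "low"], c("p2", "p6", "p4"))

  expect_error(dichotomize(c(1, 1, 1)), class = "inputError")
  expect_error(dichotomize(c(a = 1)), class = "inputError")
})

test_that("median-split imbalance is bounded by the ties at the median", {
  # with the <=-median convention the sharp bound is 2*ties - 1 (odd n)
  # and 0 when nothing ties the median (even n, distinct middle values)
  set.seed(23)
  for (i in 1:25) {
    v <- sample(1:8, sample(5:40, 1), replace = TRUE)
    names(v) <- paste0("p", seq_along(v))
    g <- dichotomize(v)
    ties <- sum(v == median(v))
    expect_lte(abs(sum(g == "low") - sum(g == "high")), max(2 * ties - 1, 0))
    if (ties == 0)
      expect_equal(sum(g == "low"), sum(g == "high"))
  }
})

test_that("stratified KM separates groups when an effect is planted", {
  worse_high <- vapply(1:20, function(i) {
    gc <- plain_cohort(400, loghr = log(1.5), seed = 700 + i)
    st <- stratifiedKM(gc, gene = "g0001")
    st$median_os[["high"]] < st$median_os[["low"]]
  }, logical(1))
  expect_gte(mean(worse_high), 0.9)
})

test_that("log-rank p is uniform when groups are survival-independent", {
  pv <- vapply(1:200, function(i) {
    gc <- plain_cohort(60, seed = 900 + i)
    stratifiedKM(gc, gene = "g0001")$logrank@p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("stratified KM rejects an empty group", {
  gc <- plain_cohort(30, seed = 2)
  asg <- setNames(factor(rep("low", 30), levels = c("low", "high")),
                  colnames(gc))
  expect_error(stratifiedKM(gc, assignment = asg), class = "inputError")
})

test_that("adjustment leaves the expression effect alone absent confounding", {
  ratio <- vapply(1:30, function(i) {
    gc <- plain_cohort(300, loghr = 0.4, seed = 1100 + i)
    adj <- multivariateOSModel(gc, "g0001")
    unadj <- gene_univariate(gc)
    adj@coef[["expression"]] / unadj$coef
  }, numeric(1))
  expect_equal(mean(ratio), 1, tolerance = 0.1)
})

test_that("a rare protective mutation has a wide adjusted interval", {
  # adjusted-model scale of the protective effect (HR ~ 0.62): with ~7%
  # carriers the interval is wide and often crosses 1
  spans <- vapply(1:12, function(i) {
    gc <- plain_cohort(311, loghr = 0.35, seed = 1300 + i,
                       covariate_effects = c(mutation = -0.48, sex = 0,
                                             age = 0, treatment = 0))
    fit <- multivariateOSModel(gc, "g0001")
    w <- waldSummary(fit)
    m <- w[w$term == "mutation_mutant", ]
    c(span1 = m$lower <= 1 && m$upper >= 1, width = m$upper / m$lower)
  }, numeric(2))
  expect_gte(mean(spans["span1", ]), 0.25)   # frequently spans 1
  expect_gt(median(spans["width", ]), 2)     # and is wide
})

test_that("flipping a binary covariate's reference negates its coefficient", {
  gc <- plain_cohort(200, loghr = 0.3, seed = 15)
  cd <- clinicalData(gc)
  z <- as.numeric(scale(exprsMatrix(gc)["g0001", ]))
  male <- as.numeric(cd$sex == "male")
  f1 <- coxFit(cd$os_months, cd$event, cbind(expr = z, sex = male))
  f2 <- coxFit(cd$os_months, cd$event, cbind(expr = z, sex = 1 - male))
  expect_equal(f1@coef[["sex"]], -f2@coef[["sex"]], tolerance = 1e-6)
  expect_equal(f1@coef[["expr"]], f2@coef[["expr"]], tolerance = 1e-6)
})

test_that("subgroup 'all' reproduces the unrestricted analysis", {
  gc <- plain_cohort(150, loghr = 0.4, seed = 18)
  sub <- subgroupAnalysis(gc, "g0001", subset = "all")
  full <- gene_univariate(gc)
  expect_equal(sub$fit@coef[["expression"]], full$coef, tolerance = 1e-12)
  expect_equal(sub$n, 150)
})

test_that("expression stays prognostic in treated and untreated subsets", {
  sig <- vapply(1:10, function(i) {
    gc <- plain_cohort(500, loghr = log(1.6), seed = 1500 + i,
                       covariate_effects = c(mutation = 0, sex = 0,
                                             age = 0, treatment = -0.69))
    p <- vapply(c("treated", "untreated"), function(s) {
      fit <- subgroupAnalysis(gc, "g0001", subset = s)$fit
      waldSummary(fit)$p[1]
    }, numeric(1))
    all(p < 0.05)
  }, logical(1))
  expect_gte(mean(sig), 0.9)
})

test_that("an event-free subset is rejected by name", {
  gc <- plain_cohort(40, seed = 19)
  cd <- clinicalData(gc)
  cd$event[cd$treatment == "yes"] <- 0L
  cd$vital_status <- ifelse(cd$event == 1, "Dead", "Alive")
  gc2 <- GliomaCohort(exprsMatrix(gc), cd)
  expect_error(subgroupAnalysis(gc2, "g0001", subset = "treated"),
               "treated", class = "inputError")
})

test_that("methylation association recovers calibrated anti-correlation", {
  cfg <- SimulationConfig(n_patients = 253, n_genes = 2, seed = 26,
                          methylation_probes = c("cgA", "cgB"),
                          methylation_gene = c(1L, 1L),
                          methylation_r = c(-0.59, -0.33))
  gc <- generateCohort(cfg)
  res <- methylationAssociation(gc, "g0001")
  expect_setequal(res$probe, c("cgA", "cgB"))
  a <- res[res$probe == "cgA", ]
  expect_equal(a$r, -0.59, tolerance = 0.05)
  expect_lt(a$p_pearson, 1e-10)
  expect_lt(a$p_mannwhitney, 1e-7)
  # anti-correlated probe: low-expression group is more methylated
  expect_gt(a$mean_beta_low, a$mean_beta_high)

  # the closed-form t-test matches the reference implementation
  b <- res[res$probe == "cgB", ]
  beta <- SummarizedExperiment::assay(methylation(gc), "beta")["cgB", ]
  ref <- cor.test(beta, exprsMatrix(gc)["g0001", ])
  expect_equal(b$t, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(b$p_pearson, ref$p.value, tolerance = 1e-8)
})

test_that("a noiseless linear decreasing transform gives r = -1", {
  gc <- plain_cohort(50, seed = 28)
  x <- exprsMatrix(gc)["g0001", ]
  beta <- matrix((max(x) - x) / diff(range(x)), nrow = 1,
                 dimnames = list("cgM", names(x)))
  gc2 <- GliomaCohort(exprsMatrix(gc), clinicalData(gc),
                      methylation = MethylationTable(beta, "g0001"))
  res <- methylationAssociation(gc2, "g0001")
  expect_equal(res$r, -1, tolerance = 1e-12)
  expect_lt(res$p_pearson, 1e-100)
})

test_that("Pearson p matches the closed form for all small n", {
  set.seed(33)
  for (n in 3:12) {
    x <- rnorm(n)
    y <- x + rnorm(n)
    r <- cor(x, y)
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    expect_equal(2 * pt(-abs(t), n - 2), cor.test(x, y)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("cohort summaries reproduce printed count/percentage arithmetic", {
  clin <- data.frame(
    patient_id = paste0("P", 1:424),
    os_months = rexp(424, 1 / 14) + 0.1,
    event = rep(c(1L, 0L), c(349, 75)),
    sex = rep(c("female", "male"), c(159, 265)),
    grade = "IV", stringsAsFactors = FALSE)
  cs <- cohortSummary(clin)
  sx <- cs$categorical$sex
  expect_equal(sx$pct_display[sx$level == "female"], "37.5")
  expect_equal(sx$pct_display[sx$level == "male"], "62.5")
  expect_equal(unname(cs$vital), c(75, 349))
  expect_equal(formatPercent(75, 424), "17.7")

  # missing values come out of the denominator
  clin2 <- data.frame(
    patient_id = paste0("Q", 1:247),
    os_months = rexp(247, 1 / 16) + 0.1, event = 1L,
    sex = c(rep("female", 67), rep("male", 107), rep(NA, 73)))
  sx2 <- cohortSummary(clin2)$categorical$sex
  expect_equal(sx2$pct_display[sx2$level == "male"], "61.5")
  expect_equal(sx2$n_missing[1], 73)

  # sub-10 percentages print two decimals
  expect_equal(formatPercent(23, 311), "7.40")
})

test_that("cross-cohort tests recover printed homogeneity statistics", {
  mk <- function(id, n3, n4, age_mu, fem, mal) {
    n <- n3 + n4
    data.frame(patient_id = paste0(id, seq_len(n)),
               os_months = rexp(n, 1 / 15) + 0.1,
               event = rbinom(n, 1, 0.85),
               grade = rep(c("III", "IV"), c(n3, n4)),
               age = rnorm(n, age_mu, 10),
               sex = c(rep("female", fem), rep("male", mal),
                       rep(NA, n - fem - mal)))
  }
  set.seed(35)
  # grade-III fractions 64/247, 21/77, 26/85 -> chi-square p rounds to 0.70
  cohorts <- list(r2 = mk("a", 64, 183, 50, 67, 107),
                  g1 = mk("b", 21, 56, 45, 25, 52),
                  g2 = mk("c", 26, 59, 42, 53, 32))
  res <- compareCohorts(cohorts)
  expect_equal(round(res$p[res$variable == "grade"], 2), 0.70)
  expect_true(all(c("age", "sex", "overall_survival") %in% res$variable))

  # duplicated cohorts: homogeneity statistics at zero
  dup <- compareCohorts(list(a = cohorts$r2, b = cohorts$r2))
  expect_equal(dup$statistic[dup$variable == "grade"], 0)
  expect_equal(dup$p[dup$variable == "grade"], 1)

  expect_error(compareCohorts(cohorts[1]), class = "inputError")
})

test_that("two-cohort sex comparison equals exhaustive Fisher enumeration", {
  set.seed(37)
  for (i in 1:20) {
    tab <- matrix(sample(0:12, 4, replace = TRUE) + 1, 2, 2)
    ref <- fisher.test(tab)$p.value
    expect_equal(fisher_enum_p(tab), ref, tolerance = 1e-10)
  }
})
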