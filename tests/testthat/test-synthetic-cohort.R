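# The cohort generator: determinism, the normalization convention, the two
# calibrations (censoring rate, methylation correlation), null soundness,
# and the multi-cohort wrapper.

test_that("same configuration gives bit-identical cohorts", {
  cfg <- SimulationConfig(n_patients = 80, n_genes = 6, seed = 42,
                          methylation_probes = "cg_test",
                          methylation_gene = 2L, methylation_r = -0.4)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(exprsMatrix(a), exprsMatrix(b))
  expect_identical(clinicalData(a), clinicalData(b))
  expect_identical(SummarizedExperiment::assay(methylation(a), "beta"),
                   SummarizedExperiment::assay(methylation(b), "beta"))
})

test_that("expression rows are median-centred on a log-like scale", {
  gc <- plain_cohort(101, n_genes = 20, seed = 5)
  med <- apply(exprsMatrix(gc), 1, median)
  expect_equal(unname(med), rep(0, 20), tolerance = 1e-12)
})

test_that("censoring calibration hits its target", {
  # single cohort at n = 1000: within the +/- 3 percentage point contract
  gc <- plain_cohort(1000, seed = 8, n_genes = 2)
  ach <- cohortTruth(gc)@censoring_achieved
  expect_gte(ach, 0.177 - 0.03)
  expect_lte(ach, 0.177 + 0.03)
  expect_identical(ach, mean(clinicalData(gc)$event == 0))

  # mean over replicates within +/- 1 pp (scaled to 40 replicates for time;
  # the calibration solves the expected fraction per realized cohort, so
  # the replicate mean concentrates quickly)
  achs <- vapply(1:40, function(i)
    cohortTruth(plain_cohort(1000, seed = 100 + i, n_genes = 1)
    )@censoring_achieved, numeric(1))
  expect_lt(abs(mean(achs) - 0.177), 0.01)
})

test_that("methylation betas live in (0,1) and hit the target correlation", {
  cfg <- SimulationConfig(n_patients = 253, n_genes = 3, seed = 10,
                          methylation_probes = c("cgA", "cgB"),
                          methylation_gene = c(1L, 1L),
                          methylation_r = c(-0.59, -0.33))
  gc <- generateCohort(cfg)
  beta <- SummarizedExperiment::assay(methylation(gc), "beta")
  expect_true(all(beta > 0 & beta < 1))
  r <- vapply(c("cgA", "cgB"), function(p)
    cor(beta[p, ], exprsMatrix(gc)["g0001", ]), numeric(1))
  expect_equal(unname(r), c(-0.59, -0.33), tolerance = 0.05)
  expect_equal(unname(cohortTruth(gc)@methylation_r_achieved), unname(r))

  # replicate mean within +/- 0.02 (scaled to 15 replicates; per-replicate
  # calibration is already within uniroot tolerance of the target)
  rr <- vapply(1:15, function(i) {
    cc <- SimulationConfig(n_patients = 253, n_genes = 1, seed = 200 + i,
                           methylation_probes = "cgA",
                           methylation_gene = 1L, methylation_r = -0.59)
    cohortTruth(generateCohort(cc))@methylation_r_achieved[["cgA"]]
  }, numeric(1))
  expect_lt(abs(mean(rr) + 0.59), 0.02)
})

test_that("unreachable calibration targets and degenerate sizes are rejected", {
  expect_error(generateCohort(SimulationConfig(n_patients = 50,
                                               censoring_target = 0)),
               class = "calibrationError")
  expect_error(
    generateCohort(SimulationConfig(n_patients = 100, n_genes = 1,
                                    methylation_probes = "cg1",
                                    methylation_gene = 1L,
                                    methylation_r = -0.97)),
    class = "calibrationError")
  expect_error(SimulationConfig(n_patients = 1))
  expect_error(SimulationConfig(planted_index = 5, planted_loghr = 1,
                                n_genes = 3))
})

test_that("with all effects null, per-gene Cox p-values are uniform", {
  gc <- plain_cohort(424, n_genes = 1000, seed = 77)
  cd <- clinicalData(gc)
  em <- exprsMatrix(gc)
  pv <- apply(em, 1, function(x) {
    f <- coxFit(cd$os_months, cd$event, as.numeric(scale(x)))
    2 * pnorm(-abs(f@coef[[1]] / f@se[[1]]))
  })
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
  expect_equal(mean(pv < 0.05), 0.05, tolerance = 0.5)
})

test_that("multi-cohort generation derives seeds and preserves singletons", {
  cfg <- SimulationConfig(n_patients = 60, n_genes = 2, seed = 3)
  single <- generateMultiCohorts(list(cfg))
  expect_identical(exprsMatrix(single[[1]]),
                   exprsMatrix(generateCohort(cfg)))

  expect_error(generateMultiCohorts(list()), class = "inputError")

  two <- generateMultiCohorts(list(cfg, cfg), master_seed = 9)
  expect_false(identical(exprsMatrix(two[[1]]), exprsMatrix(two[[2]])))
  again <- generateMultiCohorts(list(cfg, cfg), master_seed = 9)
  expect_identical(clinicalData(two[[2]]), clinicalData(again[[2]]))
})

test_that("median OS orders with the baseline scale across cohorts", {
  # five baseline scales; compare mean KM medians over replicates
  scales <- c(8, 13, 18, 23, 28)
  meds <- sapply(1:20, function(r) {
    cohorts <- generateMultiCohorts(
      lapply(scales, function(s)
        SimulationConfig(n_patients = 300, n_genes = 1, baseline_scale = s)),
      master_seed = 400 + r)
    vapply(cohorts, function(gc) {
      cd <- clinicalData(gc)
      kmEstimate(cd$os_months, cd$event)@median
    }, numeric(1))
  })
  expect_false(anyNA(meds))
  expect_true(all(diff(rowMeans(meds)) > 0))
})
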