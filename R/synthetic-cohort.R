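# Synthetic high-grade glioma cohorts with the statistical structure the
# downstream analyses assume: Weibull proportional-hazards event times,
# independent exponential censoring calibrated to a target censored
# fraction, Gaussian log-scale expression median-centred per gene, binary
# clinical covariates, and promoter-methylation beta values calibrated to a
# target Pearson correlation with a linked gene's expression.

#' Construct a methylation table
#'
#' Probes x patients beta values in [0, 1] with a mandatory probe-to-gene
#' link and an optional distance-to-TSS annotation, packaged as a
#' \code{SummarizedExperiment} with assay \code{"beta"}.
#'
#' @param beta Numeric matrix, probes x patients, values in [0, 1]; row and
#'   column names required.
#' @param gene_id Character vector: linked gene per probe.
#' @param dist_tss Optional integer distance to the transcription start
#'   site (base pairs) per probe.
#' @return A \code{SummarizedExperiment}.
#' @export
MethylationTable <- function(beta, gene_id, dist_tss = NA_integer_) {
  if (!is.matrix(beta) || is.null(rownames(beta)) || is.null(colnames(beta)))
    .inputError("beta must be a matrix with probe row names and patient column names")
  bad <- which(beta < 0 | beta > 1 | !is.finite(beta), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0)
    .inputError(sprintf("beta value out of [0, 1] at probe %s, patient %s",
                        rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]]))
  if (length(gene_id) != nrow(beta) || any(is.na(gene_id) | gene_id == ""))
    .inputError("every probe needs a gene link")
  SummarizedExperiment(
    assays = list(beta = beta),
    rowData = DataFrame(gene_id = gene_id,
                        dist_tss = rep_len(as.integer(dist_tss), nrow(beta)),
                        row.names = rownames(beta)))
}

#' Assemble a GliomaCohort from its component tables
#'
#' Joins the expression matrix and clinical table on patient id, keeping
#' the intersection; the numbers of patients dropped from each side are
#' logged with \code{message()} and recorded in
#' \code{metadata()$n_dropped}.
#'
#' @param expression Genes x patients numeric matrix (log2 scale,
#'   median-centred), with dimnames.
#' @param clinical data.frame with columns \code{patient_id},
#'   \code{os_months}, \code{event} (0/1) and any covariates.
#' @param methylation Optional \code{SummarizedExperiment} from
#'   [MethylationTable()]; subset to the joined patients.
#' @param truth Optional \linkS4class{SyntheticTruth}.
#' @return A \linkS4class{GliomaCohort}.
#' @export
GliomaCohort <- function(expression, clinical, methylation = NULL,
                         truth = NULL) {
  if (is.null(colnames(expression)))
    .inputError("expression needs patient column names")
  if (!"patient_id" %in% colnames(clinical))
    .inputError("clinical table needs a patient_id column")
  if (anyDuplicated(clinical$patient_id))
    .inputError(sprintf("duplicated patient id: %s",
                        clinical$patient_id[duplicated(clinical$patient_id)][1]))
  common <- intersect(colnames(expression), clinical$patient_id)
  if (!length(common)) .inputError("no patients shared by expression and clinical")
  n_dropped <- c(expression = ncol(expression) - length(common),
                 clinical = nrow(clinical) - length(common))
  if (any(n_dropped > 0))
    message(sprintf(
      "dropped %d expression-only and %d clinical-only patient(s)",
      n_dropped[["expression"]], n_dropped[["clinical"]]))
  clinical <- clinical[match(common, clinical$patient_id), , drop = FALSE]
  cd <- DataFrame(clinical, row.names = common)
  se <- SummarizedExperiment(
    assays = list(exprs = expression[, common, drop = FALSE]),
    colData = cd)
  if (!is.null(methylation)) {
    keep <- intersect(colnames(methylation), common)
    methylation <- methylation[, keep]
  }
  obj <- .GliomaCohort(se, methylation = methylation)
  metadata(obj)$n_dropped <- n_dropped
  if (!is.null(truth)) metadata(obj)$truth <- truth
  validObject(obj)
  obj
}

# solve the exponential censoring rate so that the expected censored
# fraction over the realised latent times hits the target
.calibrateCensoring <- function(latent, target) {
  if (target <= 0)
    .calibrationError(
      "censoring target 0 is unreachable with a finite censoring distribution")
  if (target >= 1)
    .calibrationError("censoring target must be < 1")
  f <- function(r) mean(1 - exp(-r * latent)) - target
  upper <- 1
  while (f(upper) < 0 && upper < 1e8) upper <- upper * 10
  if (f(upper) < 0)
    .calibrationError("censoring calibration failed to bracket the target")
  stats::uniroot(f, c(1e-12, upper), tol = 1e-12)$root
}

# solve the logistic slope b so that cor(plogis(-b*z + eps), z) hits the
# target, given the realised z and noise draws
.calibrateMethylation <- function(z, eps, target) {
  g <- function(b) stats::cor(stats::plogis(-b * z + eps), z) - target
  lo <- -60
  hi <- 60
  if (g(lo) < 0 || g(hi) > 0)
    .calibrationError(sprintf(
      "methylation correlation target %.2f outside the achievable range [%.2f, %.2f]",
      target, g(hi) + target, g(lo) + target))
  stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
}

#' Generate one synthetic cohort
#'
#' Expression is standard Gaussian per gene then median-centred per gene
#' (values are on a log2-like scale by construction). Event times follow a
#' Weibull proportional-hazards model whose linear predictor sums the
#' planted per-SD gene effects (applied to the standardised expression of
#' each planted gene) and the covariate effects (mutation, male sex,
#' age >= 60, treatment). Censoring times are independent exponentials
#' whose rate is solved numerically so the expected censored fraction over
#' the realised latent times equals the target; beta values for each
#' configured probe are a monotone noisy logistic transform of the linked
#' gene's expression, with the slope solved so the realised Pearson
#' correlation matches its target. Identical config (including seed) gives
#' bit-identical output.
#'
#' @param config A [SimulationConfig-class].
#' @return A \linkS4class{GliomaCohort}; the generating truth (achieved
#'   censoring fraction, achieved per-probe correlation, latent event
#'   times, calibrated nuisance parameters) is available via
#'   [cohortTruth()].
#' @examples
#' cfg <- SimulationConfig(n_patients = 100, n_genes = 10, seed = 7)
#' gc <- generateCohort(cfg)
#' cohortTruth(gc)@censoring_achieved
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@n_patients
  G <- config@n_genes
  .withSeed(config@seed, {
    expr <- matrix(stats::rnorm(G * n), nrow = G, ncol = n,
                   dimnames = list(sprintf("g%04d", seq_len(G)),
                                   sprintf("P%04d", seq_len(n))))
    expr <- expr - apply(expr, 1L, stats::median)

    ce <- config@covariate_effects
    mutation <- stats::rbinom(n, 1L, config@mutation_frequency)
    male <- stats::rbinom(n, 1L, config@sex_male_prob)
    treated <- stats::rbinom(n, 1L, config@treatment_prob)
    age <- stats::rnorm(n, config@age_median, config@age_spread)

    eta <- ce[["mutation"]] * mutation + ce[["sex"]] * male +
      ce[["age"]] * (age >= 60) + ce[["treatment"]] * treated
    for (k in seq_along(config@planted_index)) {
      zg <- as.numeric(scale(expr[config@planted_index[k], ]))
      eta <- eta + config@planted_loghr[k] * zg
    }

    # Weibull PH inversion: S(t | eta) = exp(-(t/scale)^shape * e^eta)
    u_t <- stats::runif(n)
    latent <- config@baseline_scale *
      (-log(u_t) * exp(-eta))^(1 / config@baseline_shape)
    rate <- .calibrateCensoring(latent, config@censoring_target)
    u_c <- stats::runif(n)
    cens <- -log(u_c) / rate
    os <- pmin(latent, cens)
    event <- as.integer(latent <= cens)

    meth <- NULL
    r_ach <- slope <- numeric(0)
    if (length(config@methylation_probes)) {
      beta <- matrix(0, length(config@methylation_probes), n,
                     dimnames = list(config@methylation_probes,
                                     colnames(expr)))
      slope <- r_ach <- numeric(length(config@methylation_probes))
      for (j in seq_along(config@methylation_probes)) {
        zg <- as.numeric(scale(expr[config@methylation_gene[j], ]))
        eps <- stats::rnorm(n, 0, 0.9)
        slope[j] <- .calibrateMethylation(zg, eps, config@methylation_r[j])
        beta[j, ] <- stats::plogis(-slope[j] * zg + eps)
        r_ach[j] <- stats::cor(beta[j, ], expr[config@methylation_gene[j], ])
      }
      names(slope) <- names(r_ach) <- config@methylation_probes
      meth <- MethylationTable(
        beta, gene_id = rownames(expr)[config@methylation_gene])
    }

    clinical <- data.frame(
      patient_id = colnames(expr),
      os_months = os,
      vital_status = ifelse(event == 1L, "Dead", "Alive"),
      event = event,
      age = age,
      sex = ifelse(male == 1L, "male", "female"),
      grade = "IV",
      treatment = ifelse(treated == 1L, "yes", "no"),
      mutation = ifelse(mutation == 1L, "mutant", "wild-type"),
      stringsAsFactors = FALSE)

    truth <- .SyntheticTruth(
      config = config,
      censoring_achieved = mean(event == 0L),
      censoring_rate = rate,
      methylation_r_achieved = r_ach,
      methylation_slope = slope,
      latent_times = latent)
    GliomaCohort(expr, clinical, methylation = meth, truth = truth)
  })
}

#' Generate several cohorts from one master seed
#'
#' Reproduces a multi-dataset design: each configuration is generated with
#' an independent seed derived deterministically from the master seed (or,
#' when \code{master_seed} is \code{NULL}, with its own configured seed,
#' so a singleton list reproduces [generateCohort()] exactly).
#'
#' @param configs Non-empty list of [SimulationConfig-class] objects.
#' @param master_seed Optional integer master seed.
#' @return A list of \linkS4class{GliomaCohort} objects.
#' @export
generateMultiCohorts <- function(configs, master_seed = NULL) {
  if (!length(configs)) .inputError("at least one configuration is required")
  lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    stopifnot(is(cfg, "SimulationConfig"))
    if (!is.null(master_seed))
      cfg@seed <- .deriveSeed(master_seed, paste0("cohort", i))
    generateCohort(cfg)
  })
}
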