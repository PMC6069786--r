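#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setClassUnion("SummarizedExperimentOrNULL",
              c("SummarizedExperiment", "NULL"))

# ---------------------------------------------------------------------------
# Simulation configuration
# ---------------------------------------------------------------------------

#' Configuration of a synthetic high-grade glioma cohort
#'
#' Describes the generative model for one simulated cohort: cohort and panel
#' size, which genes carry a true survival effect (log hazard ratio per 1 SD
#' of expression), log-hazard-ratios of the clinical covariates, the Weibull
#' baseline hazard, the target censoring fraction, and methylation probes
#' calibrated to a target Pearson correlation with a gene's expression.
#'
#' Defaults mirror the structure of the TCGA glioblastoma training cohort
#' this machinery emulates: n = 424 patients, ~17.7\% censoring, a rare
#' (7.4\%) favourable mutation, ~63\% male patients, age centred near 59
#' years and dichotomised downstream at 60, and two promoter probes
#' anti-correlated with the planted gene's expression (r = -0.59 and
#' -0.33).
#'
#' @slot n_patients,n_genes Cohort and gene-panel sizes.
#' @slot planted_index,planted_loghr Parallel vectors: indices of genes with
#'   a true effect and their log hazard ratios per 1 SD of expression.
#' @slot covariate_effects Named log-hazard-ratios for
#'   \code{mutation} (mutant vs wild-type), \code{sex} (male vs female),
#'   \code{age} (age >= 60 vs < 60) and \code{treatment} (treated vs not).
#' @slot mutation_frequency,sex_male_prob,treatment_prob Bernoulli
#'   probabilities for the binary covariates.
#' @slot baseline_shape,baseline_scale Weibull baseline hazard parameters
#'   (time in months).
#' @slot censoring_target Target censored fraction in (0, 1).
#' @slot methylation_probes,methylation_gene,methylation_r Parallel vectors:
#'   probe ids, linked gene index, and target Pearson correlation between
#'   beta values and that gene's expression.
#' @slot age_median,age_spread Gaussian age distribution (years).
#' @slot seed RNG seed making the cohort reproducible.
#' @seealso [generateCohort()]
#' @exportClass SimulationConfig
.SimulationConfig <- setClass("SimulationConfig",
  slots = c(
    n_patients = "integer", n_genes = "integer",
    planted_index = "integer", planted_loghr = "numeric",
    covariate_effects = "numeric",
    mutation_frequency = "numeric",
    sex_male_prob = "numeric", treatment_prob = "numeric",
    baseline_shape = "numeric", baseline_scale = "numeric",
    censoring_target = "numeric",
    methylation_probes = "character",
    methylation_gene = "integer", methylation_r = "numeric",
    age_median = "numeric", age_spread = "numeric",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  if (object@n_patients < 2L) msg <- c(msg, "n_patients must be >= 2")
  if (object@n_genes < 1L) msg <- c(msg, "n_genes must be >= 1")
  if (length(object@planted_index) != length(object@planted_loghr))
    msg <- c(msg, "planted_index and planted_loghr lengths differ")
  if (any(object@planted_index < 1L | object@planted_index > object@n_genes))
    msg <- c(msg, "planted gene indices must lie in [1, n_genes]")
  probs <- c(object@mutation_frequency, object@sex_male_prob,
             object@treatment_prob)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "covariate probabilities must lie in [0, 1]")
  if (object@censoring_target < 0 || object@censoring_target >= 1)
    msg <- c(msg, "censoring_target must lie in [0, 1)")
  if (object@baseline_shape <= 0 || object@baseline_scale <= 0)
    msg <- c(msg, "baseline shape and scale must be > 0")
  nm <- length(object@methylation_probes)
  if (length(object@methylation_gene) != nm ||
      length(object@methylation_r) != nm)
    msg <- c(msg, "methylation probe/gene/r vectors must be parallel")
  if (nm && any(object@methylation_gene < 1L |
                object@methylation_gene > object@n_genes))
    msg <- c(msg, "methylation gene indices must lie in [1, n_genes]")
  if (nm && any(abs(object@methylation_r) > 1))
    msg <- c(msg, "methylation target correlations must lie in [-1, 1]")
  if (object@age_spread <= 0) msg <- c(msg, "age_spread must be > 0")
  expected <- c("mutation", "sex", "age", "treatment")
  if (!all(expected %in% names(object@covariate_effects)))
    msg <- c(msg, "covariate_effects must name mutation, sex, age, treatment")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SimulationConfig-class Constructor with TCGA-like defaults.
#' @param n_patients,n_genes,planted_index,planted_loghr,covariate_effects,mutation_frequency,sex_male_prob,treatment_prob,baseline_shape,baseline_scale,censoring_target,methylation_probes,methylation_gene,methylation_r,age_median,age_spread,seed
#'   See the slot descriptions.
#' @return A validated \code{SimulationConfig}.
#' @export
SimulationConfig <- function(n_patients = 424L,
                             n_genes = 100L,
                             planted_index = integer(0),
                             planted_loghr = numeric(0),
                             covariate_effects = c(mutation = -0.97,
                                                   sex = 0.10,
                                                   age = 0.55,
                                                   treatment = -0.69),
                             mutation_frequency = 0.074,
                             sex_male_prob = 0.63,
                             treatment_prob = 0.5,
                             baseline_shape = 1.2,
                             baseline_scale = 18,
                             censoring_target = 0.177,
                             methylation_probes = character(0),
                             methylation_gene = integer(0),
                             methylation_r = numeric(0),
                             age_median = 59,
                             age_spread = 12,
                             seed = 1L) {
  .SimulationConfig(
    n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
    planted_index = as.integer(planted_index),
    planted_loghr = as.numeric(planted_loghr),
    covariate_effects = covariate_effects,
    mutation_frequency = mutation_frequency,
    sex_male_prob = sex_male_prob, treatment_prob = treatment_prob,
    baseline_shape = baseline_shape, baseline_scale = baseline_scale,
    censoring_target = censoring_target,
    methylation_probes = as.character(methylation_probes),
    methylation_gene = as.integer(methylation_gene),
    methylation_r = as.numeric(methylation_r),
    age_median = age_median, age_spread = age_spread,
    seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@n_patients, "patients x",
      object@n_genes, "genes\n")
  if (length(object@planted_index))
    cat("  planted genes:",
        paste0("g", object@planted_index, " (logHR ",
               signif(object@planted_loghr, 3), ")", collapse = ", "), "\n")
  cat("  censoring target:", object@censoring_target,
      " baseline Weibull(shape =", object@baseline_shape,
      ", scale =", object@baseline_scale, ")\n")
  if (length(object@methylation_probes))
    cat("  methylation probes:",
        paste0(object@methylation_probes, " -> g", object@methylation_gene,
               " (r ", signif(object@methylation_r, 2), ")",
               collapse = ", "), "\n")
  cat("  seed:", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# Synthetic truth
# ---------------------------------------------------------------------------

#' Ground truth retained alongside a simulated cohort
#'
#' Stores the generating [SimulationConfig-class] plus realised quantities
#' needed by recovery tests: the achieved censoring fraction (exactly the
#' fraction of subjects with event indicator 0), the achieved per-probe
#' expression-methylation Pearson correlation, the per-patient latent event
#' times before censoring, and the calibrated nuisance parameters
#' (exponential censoring rate and per-probe logistic slope).
#'
#' @slot config The generating configuration.
#' @slot censoring_achieved Realised censored fraction.
#' @slot censoring_rate Calibrated exponential censoring rate (per month).
#' @slot methylation_r_achieved Named realised Pearson correlations.
#' @slot methylation_slope Named calibrated logistic slopes.
#' @slot latent_times Event times before censoring (months).
#' @exportClass SyntheticTruth
.SyntheticTruth <- setClass("SyntheticTruth",
  slots = c(config = "SimulationConfig",
            censoring_achieved = "numeric",
            censoring_rate = "numeric",
            methylation_r_achieved = "numeric",
            methylation_slope = "numeric",
            latent_times = "numeric"))

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth: censoring achieved",
      sprintf("%.3f", object@censoring_achieved),
      "(target", object@config@censoring_target, ")\n")
  if (length(object@methylation_r_achieved))
    cat("  methylation r achieved:",
        paste(names(object@methylation_r_achieved),
              sprintf("%.3f", object@methylation_r_achieved),
              collapse = "; "), "\n")
})

# ---------------------------------------------------------------------------
# Cohort container
# ---------------------------------------------------------------------------

#' Glioma cohort: expression, clinical annotation and optional methylation
#'
#' A \linkS4class{SummarizedExperiment} whose single \code{"exprs"} assay
#' holds log2-scale, per-gene median-centred expression (genes x patients)
#' and whose \code{colData} is the clinical table (overall survival in
#' months, event indicator, age, sex, grade, treatment flag, mutation
#' status). An optional methylation \code{SummarizedExperiment} (assay
#' \code{"beta"}, probes x patients, \code{rowData} carrying the probe to
#' gene link) rides along in the \code{methylation} slot; simulated cohorts
#' keep their \linkS4class{SyntheticTruth} in \code{metadata(x)$truth}.
#'
#' @slot methylation \code{SummarizedExperiment} of beta values or
#'   \code{NULL}.
#' @seealso [GliomaCohort()], [generateCohort()], [clinicalData()]
#' @exportClass GliomaCohort
.GliomaCohort <- setClass("GliomaCohort",
  contains = "SummarizedExperiment",
  slots = c(methylation = "SummarizedExperimentOrNULL"))

setValidity("GliomaCohort", function(object) {
  msg <- NULL
  cd <- colData(object)
  required <- c("os_months", "event")
  miss <- setdiff(required, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("colData lacks column(s):",
                        paste(miss, collapse = ", ")))
  if (!"exprs" %in% names(assays(object)))
    msg <- c(msg, "assay 'exprs' is required")
  if ("os_months" %in% colnames(cd) && any(cd$os_months <= 0))
    msg <- c(msg, "os_months must be > 0")
  if ("event" %in% colnames(cd) && !all(cd$event %in% c(0, 1)))
    msg <- c(msg, "event must be 0/1")
  if (!is.null(object@methylation) &&
      !all(colnames(object@methylation) %in% colnames(object)))
    msg <- c(msg, "methylation patients must be a subset of cohort patients")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "GliomaCohort", function(object) {
  callNextMethod()
  cat("events:", sum(colData(object)$event), "of", ncol(object),
      sprintf("(%.1f%% censored)\n",
              100 * mean(colData(object)$event == 0)))
  if (!is.null(object@methylation))
    cat("methylation:", nrow(object@methylation), "probe(s) x",
        ncol(object@methylation), "patients\n")
})

# ---------------------------------------------------------------------------
# Survival-core result classes
# ---------------------------------------------------------------------------

#' Kaplan-Meier product-limit estimate
#'
#' Distinct event times in ascending order with the estimated survival
#' probability after each, Greenwood standard errors, risk-set and event
#' counts, and the median survival (smallest event time at which estimated
#' survival drops to 0.5 or below; \code{NA} when survival never reaches
#' 0.5).
#'
#' @slot time Distinct event times (months), ascending.
#' @slot surv Survival probability just after each event time.
#' @slot se Greenwood standard error of \code{surv}.
#' @slot n_risk,n_event Numbers at risk and events at each time.
#' @slot median Median survival in months, or \code{NA}.
#' @slot n,nevent Cohort size and total events.
#' @exportClass KMEstimate
.KMEstimate <- setClass("KMEstimate",
  slots = c(time = "numeric", surv = "numeric", se = "numeric",
            n_risk = "numeric", n_event = "numeric",
            median = "numeric", n = "integer", nevent = "integer"))

setValidity("KMEstimate", function(object) {
  msg <- NULL
  if (is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "event times must be strictly ascending")
  if (length(object@surv) && (any(object@surv < 0) || any(object@surv > 1)))
    msg <- c(msg, "survival probabilities must lie in [0, 1]")
  if (length(object@surv) > 1 && any(diff(object@surv) > 1e-12))
    msg <- c(msg, "survival must be non-increasing")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "KMEstimate", function(object) {
  cat("Kaplan-Meier estimate:", object@n, "subjects,",
      object@nevent, "events\n")
  cat("  median survival:",
      if (is.na(object@median)) "not reached"
      else paste(signif(object@median, 4), "months"), "\n")
})

#' Log-rank (Mantel-Haenszel) test result
#'
#' @slot statistic Chi-square statistic (>= 0).
#' @slot df Degrees of freedom (groups - 1).
#' @slot p Two-sided p-value.
#' @slot observed,expected Per-group observed and expected event counts.
#' @exportClass LogRankResult
.LogRankResult <- setClass("LogRankResult",
  slots = c(statistic = "numeric", df = "integer", p = "numeric",
            observed = "numeric", expected = "numeric"))

setMethod("show", "LogRankResult", function(object) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.4g\n",
              object@statistic, object@df, object@p))
})

#' Cox proportional-hazards fit
#'
#' Result of Newton-Raphson maximisation of the Cox partial likelihood.
#' Coefficients are log hazard ratios; standard errors come from the
#' inverse observed information at the optimum. Continuous expression
#' covariates fed in by the higher-level functions are standardised (mean
#' 0, SD 1) first, so their hazard ratios are per 1 SD of expression; the
#' \code{scale} slot records this.
#'
#' @slot coef Named log-hazard-ratio vector.
#' @slot se Standard errors (observed information).
#' @slot loglik Log partial likelihood at the optimum.
#' @slot loglik0 Log partial likelihood at the zero vector.
#' @slot score Score vector at the returned coefficients.
#' @slot imat Observed information matrix at the optimum.
#' @slot iter Newton iterations used.
#' @slot converged TRUE when max |score| < tol and no divergence occurred.
#' @slot ties \code{"efron"} or \code{"breslow"}.
#' @slot n,nevent Subjects and events used.
#' @slot scale Free-text note on covariate scaling (e.g. per-SD expression).
#' @seealso [coxFit()], [waldSummary()]
#' @exportClass CoxFit
.CoxFit <- setClass("CoxFit",
  slots = c(coef = "numeric", se = "numeric",
            loglik = "numeric", loglik0 = "numeric",
            score = "numeric", imat = "matrix",
            iter = "integer", converged = "logical",
            ties = "character", n = "integer", nevent = "integer",
            scale = "character"))

setValidity("CoxFit", function(object) {
  if (length(object@coef) != length(object@se))
    return("coef and se lengths differ")
  TRUE
})

setMethod("show", "CoxFit", function(object) {
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d, %s\n",
              object@ties, object@n, object@nevent,
              if (object@converged)
                sprintf("converged in %d iterations", object@iter)
              else "DID NOT CONVERGE"))
  if (object@converged) print(waldSummary(object))
  if (nzchar(object@scale)) cat("  scaling:", object@scale, "\n")
})

# ---------------------------------------------------------------------------
# Partition screen classes
# ---------------------------------------------------------------------------

#' Configuration of the random-partition Cox screen
#'
#' The screen repeatedly subsamples the cohort (each draw a simple random
#' sample without replacement, its size uniform on
#' \code{[min_size, max_size]}), fits a univariate Cox model per draw, and
#' aggregates coefficients and p-values across draws. Defaults follow the
#' published design: 500 partitions with sizes from 50 up to the full
#' cohort, two-sided significance threshold 0.05.
#'
#' @slot B Number of partitions.
#' @slot min_size,max_size Partition size range (inclusive).
#' @slot alpha Two-sided significance threshold for "fraction significant".
#' @slot ties Tie method handed to [coxFit()].
#' @slot seed RNG seed for the partition draws.
#' @exportClass PartitionConfig
.PartitionConfig <- setClass("PartitionConfig",
  slots = c(B = "integer", min_size = "integer", max_size = "integer",
            alpha = "numeric", ties = "character", seed = "integer"))

setValidity("PartitionConfig", function(object) {
  msg <- NULL
  if (object@B < 1L) msg <- c(msg, "B must be >= 1")
  if (object@min_size < 2L) msg <- c(msg, "min_size must be >= 2")
  if (object@min_size > object@max_size)
    msg <- c(msg, "min_size must be <= max_size")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (!object@ties %in% c("efron", "breslow"))
    msg <- c(msg, "ties must be 'efron' or 'breslow'")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn PartitionConfig-class Constructor with the published design
#'   as defaults.
#' @param B,min_size,max_size,alpha,ties,seed See slots.
#' @return A validated \code{PartitionConfig}.
#' @export
PartitionConfig <- function(B = 500L, min_size = 50L, max_size = 424L,
                            alpha = 0.05, ties = "efron", seed = 1L) {
  .PartitionConfig(B = as.integer(B), min_size = as.integer(min_size),
                   max_size = as.integer(max_size), alpha = alpha,
                   ties = match.arg(ties, c("efron", "breslow")),
                   seed = as.integer(seed))
}

setMethod("show", "PartitionConfig", function(object) {
  cat(sprintf(
    "PartitionConfig: B = %d, sizes U[%d, %d], alpha = %g, %s ties, seed %d\n",
    object@B, object@min_size, object@max_size, object@alpha, object@ties,
    object@seed))
})

#' Per-gene aggregate of the partition screen
#'
#' Summaries are computed over the partitions whose Cox fit converged; the
#' non-converged count is reported, never imputed. Both the mean and the
#' median of the per-partition coefficients and p-values are first-class
#' outputs.
#'
#' @slot gene Gene identifier.
#' @slot B Partitions attempted.
#' @slot n_converged Partitions whose fit converged.
#' @slot coef_mean,coef_median,p_mean,p_median Aggregates over converged
#'   partitions.
#' @slot frac_significant Fraction of converged partitions with p < alpha.
#' @slot alpha Threshold used.
#' @slot records Per-partition (size, coef, p, converged) table
#'   (\code{DataFrame}), retained when requested.
#' @exportClass PartitionSummary
.PartitionSummary <- setClass("PartitionSummary",
  slots = c(gene = "character", B = "integer", n_converged = "integer",
            coef_mean = "numeric", coef_median = "numeric",
            p_mean = "numeric", p_median = "numeric",
            frac_significant = "numeric", alpha = "numeric",
            records = "DataFrame"))

setValidity("PartitionSummary", function(object) {
  msg <- NULL
  if (object@frac_significant < 0 || object@frac_significant > 1)
    msg <- c(msg, "frac_significant must lie in [0, 1]")
  cnt <- object@frac_significant * object@n_converged
  if (abs(cnt - round(cnt)) > 1e-8)
    msg <- c(msg, "frac_significant * n_converged must be an integer count")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "PartitionSummary", function(object) {
  cat(sprintf("Partition screen for %s: %d/%d fits converged\n",
              object@gene, object@n_converged, object@B))
  cat(sprintf(
    "  coef mean %.4g / median %.4g; p mean %.3g / median %.3g\n",
    object@coef_mean, object@coef_median, object@p_mean, object@p_median))
  cat(sprintf("  fraction significant at alpha = %g: %.3f\n",
              object@alpha, object@frac_significant))
})
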