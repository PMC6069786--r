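# Random-partition robustness screening: repeatedly subsample the cohort,
# fit a univariate Cox model per subsample, and aggregate coefficients and
# p-values across subsamples as a stability criterion for marker selection.
#
# "Partition" here means a simple random sample WITHOUT replacement whose
# size is drawn uniformly from [min_size, max_size]: sizes up to the full
# cohort are allowed, which rules out a disjoint-split reading. The same
# partitions are shared by every gene (drawn once from the partition seed),
# so results never depend on gene order.

#' Draw the random partitions
#'
#' Each partition is a simple random sample of patient indices without
#' replacement; its size is uniform on the integers
#' \code{[min_size, max_size]}. Deterministic given \code{config@seed}.
#'
#' @param n Cohort size.
#' @param config A [PartitionConfig-class]; \code{max_size} is capped at
#'   \code{n}.
#' @return List of \code{B} sorted integer index vectors.
#' @export
drawPartitions <- function(n, config) {
  stopifnot(is(config, "PartitionConfig"))
  validObject(config)
  if (config@min_size > n)
    .inputError(sprintf("min_size (%d) exceeds the cohort size (%d)",
                        config@min_size, n))
  max_size <- min(config@max_size, n)
  .withSeed(config@seed, {
    sizes <- if (config@min_size == max_size)
      rep.int(config@min_size, config@B)
    else
      sample(seq.int(config@min_size, max_size), config@B, replace = TRUE)
    lapply(sizes, function(s) sort(sample.int(n, s)))
  })
}

# Univariate per-partition Cox fits for one standardized expression vector.
# z is standardized on the FULL cohort so per-partition coefficients share
# the per-SD scale. Returns a DataFrame of per-partition records.
.partitionFits <- function(z, time, event, partitions, ties) {
  B <- length(partitions)
  size <- coef <- p <- rep(NA_real_, B)
  conv <- logical(B)
  for (b in seq_len(B)) {
    idx <- partitions[[b]]
    size[b] <- length(idx)
    if (sum(event[idx]) < 1 || diff(range(z[idx])) == 0) next
    fit <- coxFit(time[idx], event[idx], z[idx], ties = ties)
    conv[b] <- fit@converged
    if (fit@converged) {
      coef[b] <- fit@coef[[1L]]
      zstat <- fit@coef[[1L]] / fit@se[[1L]]
      p[b] <- 2 * stats::pnorm(-abs(zstat))
    }
  }
  DataFrame(size = as.integer(size), coef = coef, p = p, converged = conv)
}

.summarizePartitions <- function(gene, rec, alpha, keep_records) {
  ok <- rec$converged
  if (!any(ok))
    .convergenceError(sprintf("no partition Cox fit converged for %s", gene))
  .PartitionSummary(
    gene = gene, B = nrow(rec), n_converged = sum(ok),
    coef_mean = mean(rec$coef[ok]), coef_median = stats::median(rec$coef[ok]),
    p_mean = mean(rec$p[ok]), p_median = stats::median(rec$p[ok]),
    frac_significant = mean(rec$p[ok] < alpha), alpha = alpha,
    records = if (keep_records) rec else DataFrame())
}

#' Partition screen for a single gene
#'
#' Fits one univariate Cox model (overall survival against the gene's
#' full-cohort-standardised expression) per partition and aggregates the
#' converged fits: mean and median coefficient, mean and median p-value,
#' and the fraction of partitions significant at \code{alpha}.
#' Non-convergent partitions are excluded from the aggregates and counted,
#' never imputed.
#'
#' @param cohort A \linkS4class{GliomaCohort}.
#' @param gene Gene id (row name) to screen.
#' @param config A [PartitionConfig-class].
#' @param partitions Optional pre-drawn partitions (from
#'   [drawPartitions()]); drawn from \code{config} when \code{NULL}.
#' @param keep_records Retain the per-partition (size, coef, p) table in
#'   the result?
#' @return A \linkS4class{PartitionSummary}.
#' @export
partitionCoxScreen <- function(cohort, gene, config = PartitionConfig(),
                               partitions = NULL, keep_records = TRUE) {
  stopifnot(is(cohort, "GliomaCohort"))
  expr <- exprsMatrix(cohort)
  if (!gene %in% rownames(expr))
    .inputError(sprintf("gene '%s' is not in the expression matrix", gene))
  cd <- colData(cohort)
  if (is.null(partitions))
    partitions <- drawPartitions(ncol(cohort), config)
  z <- as.numeric(scale(expr[gene, ]))
  rec <- .partitionFits(z, cd$os_months, cd$event, partitions, config@ties)
  .summarizePartitions(gene, rec, config@alpha, keep_records)
}

#' Genome-wide partition screen
#'
#' For every gene: a full-cohort univariate Cox fit (the primary ranking
#' key) plus the partition aggregate, with a Benjamini-Hochberg adjusted
#' column for reference (raw p-values remain the ranking key). One set of
#' partitions, drawn once from \code{config@seed}, is shared by all genes.
#'
#' @inheritParams partitionCoxScreen
#' @param genes Optional subset of gene ids; default all rows.
#' @return A \code{DataFrame} sorted by full-cohort p ascending, with
#'   columns \code{gene}, \code{coef_full}, \code{se_full}, \code{hr_full},
#'   \code{p_full}, \code{p_adj}, \code{coef_mean}, \code{coef_median},
#'   \code{p_mean}, \code{p_median}, \code{frac_significant},
#'   \code{n_converged}, \code{n_partitions}, \code{converged_full}. The
#'   screen parameters are recorded in \code{metadata()}.
#' @export
genomeScreen <- function(cohort, config = PartitionConfig(), genes = NULL) {
  stopifnot(is(cohort, "GliomaCohort"))
  expr <- exprsMatrix(cohort)
  if (is.null(genes)) genes <- rownames(expr)
  if (!length(genes)) .inputError("at least one gene is required")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    .inputError(paste("unknown gene(s):", paste(missing, collapse = ", ")))
  cd <- colData(cohort)
  partitions <- drawPartitions(ncol(cohort), config)

  one <- function(g) {
    z <- as.numeric(scale(expr[g, ]))
    full <- tryCatch(coxFit(cd$os_months, cd$event, z, ties = config@ties,
                            scale_note = "expression per 1 SD"),
                     gliomaScreenError = function(e) NULL)
    ok_full <- !is.null(full) && full@converged
    ps <- tryCatch(
      .summarizePartitions(
        g, .partitionFits(z, cd$os_months, cd$event, partitions,
                          config@ties),
        config@alpha, keep_records = FALSE),
      gliomaScreenError = function(e) NULL)
    data.frame(
      gene = g,
      coef_full = if (ok_full) full@coef[[1L]] else NA_real_,
      se_full = if (ok_full) full@se[[1L]] else NA_real_,
      hr_full = if (ok_full) exp(full@coef[[1L]]) else NA_real_,
      p_full = if (ok_full)
        2 * stats::pnorm(-abs(full@coef[[1L]] / full@se[[1L]]))
      else NA_real_,
      coef_mean = if (is.null(ps)) NA_real_ else ps@coef_mean,
      coef_median = if (is.null(ps)) NA_real_ else ps@coef_median,
      p_mean = if (is.null(ps)) NA_real_ else ps@p_mean,
      p_median = if (is.null(ps)) NA_real_ else ps@p_median,
      frac_significant = if (is.null(ps)) NA_real_ else ps@frac_significant,
      n_converged = if (is.null(ps)) 0L else ps@n_converged,
      converged_full = ok_full,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(genes, one))
  tab$p_adj <- stats::p.adjust(tab$p_full, method = "BH")
  tab <- tab[order(tab$p_full), ]
  out <- DataFrame(tab, row.names = NULL)
  out$n_partitions <- config@B
  metadata(out) <- list(B = config@B, min_size = config@min_size,
                        max_size = config@max_size, alpha = config@alpha,
                        ties = config@ties, seed = config@seed)
  out
}

#' Select robust genes from a screen table
#'
#' Keeps genes whose partition behaviour is stable: fraction of
#' significant partitions at or above \code{fraction_threshold} and median
#' partition p-value at or below \code{p_threshold}.
#'
#' @param table Output of [genomeScreen()].
#' @param fraction_threshold Minimum fraction significant (default 0.9).
#' @param p_threshold Maximum median partition p (default 0.05).
#' @return Character vector of selected gene ids.
#' @export
selectRobust <- function(table, fraction_threshold = 0.9,
                         p_threshold = 0.05) {
  keep <- !is.na(table$frac_significant) &
    table$frac_significant >= fraction_threshold &
    !is.na(table$p_median) & table$p_median <= p_threshold
  as.character(table$gene[keep])
}
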