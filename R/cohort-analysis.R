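# Downstream analyses: expression dichotomization, stratified Kaplan-Meier
# reports, multivariate Cox adjustment, treatment / mutation subgroup
# analysis, promoter methylation association, and Table-1 style cohort
# summaries with cross-cohort homogeneity tests.

.isMissing <- function(x) {
  is.na(x) | (is.character(x) & (x == "" | toupper(x) == "NA" |
                                   tolower(x) == "missing"))
}

#' Split patients into low/high expression groups
#'
#' Median rule: values at or below the median go to the low group (ties at
#' the median are low by convention). Lower-tertile rule: the
#' \code{floor(n/3)} smallest values form the low group, ties broken by
#' stable patient-id order.
#'
#' @param x Named numeric vector (one gene's expression per patient).
#' @param rule \code{"median"} or \code{"lower-tertile"}.
#' @return Factor with levels \code{low}, \code{high}, named by patient,
#'   with attributes \code{rule} and \code{cut} (the cut value on the
#'   expression scale).
#' @examples
#' dichotomize(c(a = 1, b = 2, c = 3, d = 4))
#' @export
dichotomize <- function(x, rule = c("median", "lower-tertile")) {
  rule <- match.arg(rule)
  keep <- !.isMissing(x)
  x <- x[keep]
  if (length(x) < 2L)
    .inputError("at least two patients with non-missing expression required")
  if (diff(range(x)) == 0)
    .inputError("all expression values identical: no cut exists")
  if (is.null(names(x))) names(x) <- as.character(seq_along(x))
  if (rule == "median") {
    cut <- stats::median(x)
    lab <- ifelse(x <= cut, "low", "high")
  } else {
    k <- floor(length(x) / 3)
    if (k < 1L) .inputError("cohort too small for a tertile split")
    ord <- order(x, names(x))
    lab <- rep("high", length(x))
    lab[ord[seq_len(k)]] <- "low"
    cut <- x[ord[k]]
  }
  out <- factor(lab, levels = c("low", "high"))
  names(out) <- names(x)
  attr(out, "rule") <- rule
  attr(out, "cut") <- unname(cut)
  out
}

.assignmentFor <- function(cohort, gene, rule, patients = NULL) {
  expr <- exprsMatrix(cohort)
  if (!gene %in% rownames(expr))
    .inputError(sprintf("gene '%s' is not in the expression matrix", gene))
  v <- expr[gene, ]
  if (!is.null(patients)) v <- v[patients]
  dichotomize(v, rule)
}

#' Stratified Kaplan-Meier report
#'
#' Combines per-group product-limit estimates, the two-group (or K-group)
#' log-rank test, and per-group median overall survival into one report.
#'
#' @param cohort A \linkS4class{GliomaCohort}.
#' @param assignment Group factor named by patient id (e.g. from
#'   [dichotomize()]); alternatively supply \code{gene} (+ \code{rule}) and
#'   the split is computed here.
#' @param gene,rule Used when \code{assignment} is \code{NULL}.
#' @return List with elements \code{km} (named list of
#'   \linkS4class{KMEstimate}), \code{logrank}
#'   (\linkS4class{LogRankResult}), \code{median_os} (named numeric, NA =
#'   not reached) and \code{n} (group sizes).
#' @export
stratifiedKM <- function(cohort, assignment = NULL, gene = NULL,
                         rule = "median") {
  stopifnot(is(cohort, "GliomaCohort"))
  if (is.null(assignment)) {
    if (is.null(gene)) .inputError("supply either an assignment or a gene")
    assignment <- .assignmentFor(cohort, gene, rule)
  }
  ids <- intersect(colnames(cohort), names(assignment))
  if (!length(ids)) .inputError("assignment names do not match patient ids")
  assignment <- droplevels(factor(assignment[ids]))
  if (nlevels(assignment) < 2L)
    .inputError("both groups must be non-empty")
  cd <- colData(cohort)[ids, ]
  km <- lapply(levels(assignment), function(g) {
    sel <- assignment == g
    kmEstimate(cd$os_months[sel], cd$event[sel])
  })
  names(km) <- levels(assignment)
  lr <- logrankTest(cd$os_months, cd$event, assignment)
  list(km = km,
       logrank = lr,
       median_os = vapply(km, function(k) k@median, numeric(1)),
       n = table(assignment))
}

#' Multivariate Cox model for overall survival
#'
#' Joint Cox model of overall survival on a gene's expression (kept
#' continuous, standardised to SD 1 on the analysed cases, so its hazard
#' ratio is per 1 SD) plus categorical clinical covariates: mutation
#' status (mutant vs wild-type reference), sex (male vs female reference)
#' and age dichotomised at \code{age_cutoff} (default 60). Cases missing
#' any used covariate are dropped with a logged count.
#'
#' @param cohort A \linkS4class{GliomaCohort}.
#' @param gene Gene id kept continuous in the model.
#' @param covariates Subset of \code{c("mutation", "sex", "age",
#'   "treatment")}.
#' @param age_cutoff Years; default 60.
#' @param ties Tie method for [coxFit()].
#' @return A \linkS4class{CoxFit}; inspect with [waldSummary()].
#' @export
multivariateOSModel <- function(cohort, gene,
                                covariates = c("mutation", "sex", "age"),
                                age_cutoff = 60, ties = "efron") {
  stopifnot(is(cohort, "GliomaCohort"))
  covariates <- match.arg(covariates,
                          c("mutation", "sex", "age", "treatment"),
                          several.ok = TRUE)
  cd <- clinicalData(cohort)
  expr <- exprsMatrix(cohort)
  if (!gene %in% rownames(expr))
    .inputError(sprintf("gene '%s' is not in the expression matrix", gene))
  cols <- list(expression = expr[gene, rownames(cd)])
  if ("mutation" %in% covariates)
    cols$mutation_mutant <- ifelse(.isMissing(cd$mutation), NA,
                                   as.numeric(cd$mutation == "mutant"))
  if ("sex" %in% covariates)
    cols$sex_male <- ifelse(.isMissing(cd$sex), NA,
                            as.numeric(cd$sex == "male"))
  if ("age" %in% covariates)
    cols$age_ge_cutoff <- ifelse(.isMissing(cd$age), NA,
                                 as.numeric(cd$age >= age_cutoff))
  if ("treatment" %in% covariates)
    cols$treated <- ifelse(.isMissing(cd$treatment), NA,
                           as.numeric(cd$treatment == "yes"))
  X <- do.call(cbind, cols)
  complete <- stats::complete.cases(X)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(sprintf("multivariateOSModel: dropped %d case(s) with missing covariates",
                    n_dropped))
  X <- X[complete, , drop = FALSE]
  tm <- cd$os_months[complete]
  ev <- cd$event[complete]
  if (sum(ev) < 2) .inputError("fewer than 2 events after dropping missing cases")
  X[, "expression"] <- as.numeric(scale(X[, "expression"]))
  coxFit(tm, ev, X, ties = ties,
         scale_note = sprintf(
           "expression per 1 SD of the %d analysed cases; age cutoff %g",
           nrow(X), age_cutoff))
}

#' Subgroup survival analysis
#'
#' Restricts the cohort to a named subgroup (temozolomide-treated,
#' untreated, or mutation wild-type patients), recomputes the expression
#' dichotomization within the subgroup, and reports both the continuous
#' univariate Cox fit (per-SD within the subgroup) and the stratified
#' Kaplan-Meier comparison.
#'
#' @param cohort A \linkS4class{GliomaCohort}.
#' @param gene Gene id.
#' @param subset One of \code{"treated"}, \code{"untreated"},
#'   \code{"mutation-wild-type"}, \code{"all"}.
#' @param rule Dichotomization rule, see [dichotomize()].
#' @param ties Tie method for [coxFit()].
#' @return List with \code{subset}, \code{n}, \code{fit}
#'   (\linkS4class{CoxFit}) and \code{km} (a [stratifiedKM()] report).
#' @export
subgroupAnalysis <- function(cohort, gene,
                             subset = c("treated", "untreated",
                                        "mutation-wild-type", "all"),
                             rule = "median", ties = "efron") {
  stopifnot(is(cohort, "GliomaCohort"))
  subset <- match.arg(subset)
  cd <- clinicalData(cohort)
  sel <- switch(subset,
                "treated" = !.isMissing(cd$treatment) & cd$treatment == "yes",
                "untreated" = !.isMissing(cd$treatment) & cd$treatment == "no",
                "mutation-wild-type" =
                  !.isMissing(cd$mutation) & cd$mutation == "wild-type",
                "all" = rep(TRUE, nrow(cd)))
  ids <- rownames(cd)[sel]
  if (!length(ids))
    .inputError(sprintf("subset rule '%s' selects no patients", subset))
  if (sum(cd$event[sel]) < 2)
    .inputError(sprintf("subset rule '%s' leaves fewer than 2 events", subset))
  sub <- cohort[, ids]
  expr <- exprsMatrix(sub)[gene, ]
  fit <- coxFit(colData(sub)$os_months, colData(sub)$event,
                as.numeric(scale(expr)), ties = ties,
                scale_note = sprintf("expression per 1 SD within '%s' subset",
                                     subset))
  names(fit@coef) <- names(fit@se) <- "expression"
  list(subset = subset, n = length(ids), fit = fit,
       km = stratifiedKM(sub, gene = gene, rule = rule))
}

#' Methylation-expression association per probe
#'
#' For each probe linked to the gene: the Pearson correlation between beta
#' values and the gene's expression with its exact t-test
#' (t = r sqrt(n-2) / sqrt(1-r^2), two-sided), and a Mann-Whitney
#' comparison of beta values between the low- and high-expression groups
#' (exact enumeration when the pooled n is <= 20 with no ties, normal
#' approximation with tie correction otherwise).
#'
#' @param cohort A \linkS4class{GliomaCohort} with methylation data.
#' @param gene Gene id.
#' @param probes Probe ids; default all probes annotated to \code{gene}.
#' @param assignment Optional low/high factor; computed from \code{gene}
#'   by \code{rule} over the methylation-profiled patients when
#'   \code{NULL}.
#' @param rule Dichotomization rule.
#' @return \code{DataFrame}: per probe \code{n}, Pearson \code{r},
#'   \code{t}, \code{p_pearson}, Mann-Whitney statistic \code{mw_W},
#'   \code{p_mannwhitney}, and group mean beta values.
#' @export
methylationAssociation <- function(cohort, gene, probes = NULL,
                                   assignment = NULL, rule = "median") {
  stopifnot(is(cohort, "GliomaCohort"))
  meth <- methylation(cohort)
  if (is.null(meth)) .inputError("cohort carries no methylation data")
  if (is.null(probes))
    probes <- rownames(meth)[rowData(meth)$gene_id == gene]
  if (!length(probes))
    .inputError(sprintf("no methylation probe is annotated to '%s'", gene))
  missing <- setdiff(probes, rownames(meth))
  if (length(missing))
    .inputError(paste("unknown probe(s):", paste(missing, collapse = ", ")))
  pats <- colnames(meth)
  expr <- exprsMatrix(cohort)[gene, pats]
  if (length(pats) < 3L) .inputError("at least 3 paired observations required")
  if (is.null(assignment)) assignment <- dichotomize(expr, rule)
  assignment <- assignment[pats]
  beta <- assay(meth, "beta")[probes, pats, drop = FALSE]

  one <- function(pr) {
    b <- beta[pr, ]
    n <- sum(!is.na(b) & !is.na(expr))
    if (stats::sd(b) == 0 || stats::sd(expr) == 0)
      .inputError(sprintf("zero variance: correlation undefined for %s", pr))
    r <- stats::cor(b, expr)
    t <- r * sqrt(n - 2) / sqrt(max(1 - r^2, 0))
    p_r <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), n - 2)
    lowv <- b[assignment == "low"]
    highv <- b[assignment == "high"]
    exact <- (length(lowv) + length(highv)) <= 20 &&
      !anyDuplicated(c(lowv, highv))
    mw <- suppressWarnings(
      stats::wilcox.test(lowv, highv, exact = exact))
    data.frame(probe = pr, gene = gene, n = n, r = r, t = t,
               p_pearson = p_r,
               mw_W = unname(mw$statistic), p_mannwhitney = mw$p.value,
               mean_beta_low = mean(lowv), mean_beta_high = mean(highv),
               stringsAsFactors = FALSE)
  }
  DataFrame(do.call(rbind, lapply(probes, one)), row.names = NULL)
}

#' Table-1 style cohort summary
#'
#' Counts and percentages per categorical variable (missing values
#' excluded from the denominators), median age with range, Kaplan-Meier
#' median overall survival, and alive/dead counts. Percentages are
#' display-formatted by [formatPercent()] (one decimal, two when below
#' 10).
#'
#' @param x A \linkS4class{GliomaCohort} or a clinical data.frame with at
#'   least \code{os_months} and \code{event}.
#' @return List with \code{n}, \code{age_median}, \code{age_range},
#'   \code{median_os}, \code{vital} (alive/dead counts) and
#'   \code{categorical}: per variable a data.frame of level, count,
#'   pct (numeric) and pct_display.
#' @export
cohortSummary <- function(x) {
  cd <- if (is(x, "GliomaCohort")) clinicalData(x) else x
  stopifnot(all(c("os_months", "event") %in% colnames(cd)))
  vars <- intersect(c("sex", "grade", "treatment", "mutation",
                      "methylation_status", "subtype"), colnames(cd))
  categorical <- lapply(vars, function(v) {
    val <- cd[[v]]
    miss <- .isMissing(val)
    tab <- table(val[!miss])
    denom <- sum(!miss)
    data.frame(level = names(tab), count = as.integer(tab),
               pct = 100 * as.integer(tab) / denom,
               pct_display = formatPercent(as.integer(tab), denom),
               n_missing = sum(miss),
               stringsAsFactors = FALSE)
  })
  names(categorical) <- vars
  km <- kmEstimate(cd$os_months, cd$event)
  age <- if ("age" %in% colnames(cd)) cd$age[!.isMissing(cd$age)] else numeric(0)
  list(n = nrow(cd),
       age_median = if (length(age)) stats::median(age) else NA_real_,
       age_range = if (length(age)) range(age) else c(NA_real_, NA_real_),
       median_os = km@median,
       vital = c(alive = sum(cd$event == 0), dead = sum(cd$event == 1)),
       categorical = categorical)
}

#' Cross-cohort homogeneity tests
#'
#' Chi-square homogeneity of the grade mix (falling back to Fisher's exact
#' test, with a logged note, when any expected cell is below 1),
#' Kruskal-Wallis on age, Fisher's exact test on sex for two cohorts
#' (chi-square for more), and a multi-cohort log-rank test on overall
#' survival.
#'
#' @param cohorts Named or unnamed list of \linkS4class{GliomaCohort}
#'   objects or clinical data.frames (>= 2).
#' @return data.frame with one row per comparison: \code{variable},
#'   \code{test}, \code{statistic}, \code{df}, \code{p}.
#' @export
compareCohorts <- function(cohorts) {
  if (length(cohorts) < 2L) .inputError("at least two cohorts are required")
  tabs <- lapply(cohorts, function(x)
    if (is(x, "GliomaCohort")) clinicalData(x) else x)
  nm <- names(tabs)
  if (is.null(nm)) nm <- paste0("cohort", seq_along(tabs))
  rows <- list()
  addRow <- function(variable, test, statistic, df, p)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, test = test, statistic = statistic,
      df = df, p = p, stringsAsFactors = FALSE)

  contingency <- function(var) {
    lv <- lapply(tabs, function(t) {
      v <- t[[var]]
      v[!.isMissing(v)]
    })
    lev <- sort(unique(unlist(lv)))
    sapply(lv, function(v) table(factor(v, levels = lev)))
  }

  if (all(vapply(tabs, function(t) "grade" %in% colnames(t), logical(1)))) {
    ct <- contingency("grade")
    if (nrow(ct) >= 2) {
      cs <- suppressWarnings(stats::chisq.test(ct, correct = FALSE))
      if (any(cs$expected < 1)) {
        message("compareCohorts: expected grade cell < 1, using Fisher's exact test")
        fe <- stats::fisher.test(ct)
        addRow("grade", "fisher-exact", NA_real_, NA_real_, fe$p.value)
      } else {
        addRow("grade", "chi-square", unname(cs$statistic),
               unname(cs$parameter), cs$p.value)
      }
    }
  }
  if (all(vapply(tabs, function(t) "age" %in% colnames(t), logical(1)))) {
    age <- unlist(lapply(tabs, function(t) t$age))
    g <- factor(rep(nm, vapply(tabs, nrow, integer(1))))
    keep <- !.isMissing(age)
    kw <- stats::kruskal.test(age[keep], g[keep])
    addRow("age", "kruskal-wallis", unname(kw$statistic),
           unname(kw$parameter), kw$p.value)
  }
  if (all(vapply(tabs, function(t) "sex" %in% colnames(t), logical(1)))) {
    ct <- contingency("sex")
    if (length(tabs) == 2L && nrow(ct) == 2L) {
      fe <- stats::fisher.test(ct)
      addRow("sex", "fisher-exact", NA_real_, NA_real_, fe$p.value)
    } else {
      cs <- suppressWarnings(stats::chisq.test(ct, correct = FALSE))
      addRow("sex", "chi-square", unname(cs$statistic),
             unname(cs$parameter), cs$p.value)
    }
  }
  tm <- unlist(lapply(tabs, function(t) t$os_months))
  ev <- unlist(lapply(tabs, function(t) t$event))
  g <- factor(rep(nm, vapply(tabs, nrow, integer(1))))
  lr <- logrankTest(tm, ev, g)
  addRow("overall_survival", "log-rank", lr@statistic, lr@df, lr@p)
  do.call(rbind, rows)
}
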