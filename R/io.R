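# Tab-separated file formats and the pipeline entry point. All tables are
# plain TSV with a header row; numerics are written with 17 significant
# digits so write -> read round-trips reproduce doubles exactly.

.fmtNum <- function(x) sprintf("%.17g", x)

.writeTSV <- function(df, path, header_lines = character(0)) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .fmtNum)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a clinical table
#'
#' Tab-separated with a header; mandatory columns \code{patient_id},
#' \code{os_months}, \code{vital_status}. \code{vital_status} is parsed
#' case-insensitively (\code{alive} -> event 0, \code{dead} -> event 1).
#' Rows lacking survival time, a parseable vital status, or with
#' non-positive survival time are excluded at load with a logged count
#' (also recorded in \code{attr(x, "n_excluded")}). Duplicate patient ids
#' are a hard error.
#'
#' @param path File path.
#' @return data.frame with an added 0/1 \code{event} column.
#' @export
readClinicalTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE)
  mandatory <- c("patient_id", "os_months", "vital_status")
  miss <- setdiff(mandatory, colnames(df))
  if (length(miss))
    .inputError(paste("clinical table lacks mandatory column(s):",
                      paste(miss, collapse = ", ")))
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup))
    .inputError(sprintf("duplicated patient id: %s", dup[1]))
  vs <- tolower(df$vital_status)
  event <- ifelse(vs == "dead", 1L, ifelse(vs == "alive", 0L, NA_integer_))
  os <- suppressWarnings(as.numeric(df$os_months))
  bad <- is.na(os) | os <= 0 | is.na(event)
  if (any(bad))
    message(sprintf(
      "readClinicalTable: excluded %d row(s) lacking usable survival data",
      sum(bad)))
  df <- df[!bad, , drop = FALSE]
  df$os_months <- os[!bad]
  df$event <- event[!bad]
  rownames(df) <- NULL
  attr(df, "n_excluded") <- sum(bad)
  df
}

#' Read a gene-by-patient expression matrix
#'
#' First column \code{gene_id}, remaining columns one per patient. Genes
#' with any missing value are dropped and counted
#' (\code{attr(x, "n_dropped_genes")}).
#'
#' @param path File path.
#' @param normalize \code{"none"} (pass through),
#'   \code{"median-center"} (subtract the per-gene median),
#'   \code{"log2-median-center"} (log2 then median-centre; requires
#'   strictly positive values) or \code{"median-center-log2"} (the
#'   alternate order some sources describe; requires positivity after
#'   centring, so rarely appropriate — provided as an explicit toggle).
#' @return Numeric matrix, genes x patients.
#' @export
readExpressionMatrix <- function(path,
                                 normalize = c("none", "median-center",
                                               "log2-median-center",
                                               "median-center-log2")) {
  normalize <- match.arg(normalize)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE)
  if (colnames(df)[1] != "gene_id")
    .inputError("first expression column must be gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene_id
  incomplete <- !stats::complete.cases(m)
  if (any(incomplete)) {
    message(sprintf("readExpressionMatrix: dropped %d gene(s) with missing values",
                    sum(incomplete)))
    m <- m[!incomplete, , drop = FALSE]
  }
  center <- function(x) x - apply(x, 1L, stats::median)
  lg2 <- function(x) {
    if (any(x <= 0))
      .inputError("log2 normalization requires strictly positive values")
    log2(x)
  }
  m <- switch(normalize,
              "none" = m,
              "median-center" = center(m),
              "log2-median-center" = center(lg2(m)),
              "median-center-log2" = lg2(center(m)))
  const <- apply(m, 1L, function(v) diff(range(v)) == 0)
  if (any(const) && normalize != "none")
    message(sprintf("readExpressionMatrix: %d constant gene(s) after normalization",
                    sum(const)))
  attr(m, "n_dropped_genes") <- sum(incomplete)
  m
}

#' Read a methylation table
#'
#' Columns \code{probe_id}, \code{gene_id}, optional \code{dist_tss},
#' then one beta-value column per patient. Beta values outside [0, 1] are
#' an error naming the probe and patient; a probe without a gene link is
#' an error.
#'
#' @param path File path.
#' @return A \code{SummarizedExperiment} (see [MethylationTable()]).
#' @export
readMethylationTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE)
  need <- c("probe_id", "gene_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    .inputError(paste("methylation table lacks column(s):",
                      paste(miss, collapse = ", ")))
  has_tss <- "dist_tss" %in% colnames(df)
  patcols <- setdiff(colnames(df), c(need, "dist_tss"))
  beta <- as.matrix(df[, patcols, drop = FALSE])
  storage.mode(beta) <- "double"
  rownames(beta) <- df$probe_id
  MethylationTable(beta, gene_id = df$gene_id,
                   dist_tss = if (has_tss) df$dist_tss else NA_integer_)
}

#' Write a cohort to tab-separated files
#'
#' Writes \code{clinical.tsv}, \code{expression.tsv}, and, when present,
#' \code{methylation.tsv} and a \code{truth.txt} key-value file, into
#' \code{dir}. Numeric values carry 17 significant digits so
#' [readClinicalTable()] / [readExpressionMatrix()] /
#' [readMethylationTable()] reproduce them exactly.
#'
#' @param cohort A \linkS4class{GliomaCohort}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "GliomaCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(clinical = file.path(dir, "clinical.tsv"),
             expression = file.path(dir, "expression.tsv"))
  cd <- clinicalData(cohort)
  .writeTSV(cd, paths[["clinical"]])
  em <- exprsMatrix(cohort)
  .writeTSV(data.frame(gene_id = rownames(em), em, check.names = FALSE),
            paths[["expression"]])
  meth <- methylation(cohort)
  if (!is.null(meth)) {
    paths[["methylation"]] <- file.path(dir, "methylation.tsv")
    .writeTSV(data.frame(probe_id = rownames(meth),
                         gene_id = rowData(meth)$gene_id,
                         dist_tss = rowData(meth)$dist_tss,
                         assay(meth, "beta"), check.names = FALSE),
              paths[["methylation"]])
  }
  truth <- cohortTruth(cohort)
  if (!is.null(truth)) {
    paths[["truth"]] <- file.path(dir, "truth.txt")
    cfg <- truth@config
    kv <- c(n_patients = cfg@n_patients, n_genes = cfg@n_genes,
            seed = cfg@seed,
            censoring_target = .fmtNum(cfg@censoring_target),
            censoring_achieved = .fmtNum(truth@censoring_achieved),
            censoring_rate = .fmtNum(truth@censoring_rate))
    if (length(truth@methylation_r_achieved))
      kv <- c(kv, stats::setNames(
        .fmtNum(truth@methylation_r_achieved),
        paste0("methylation_r_achieved.",
               names(truth@methylation_r_achieved))))
    if (length(cfg@planted_index))
      kv <- c(kv,
              planted_index = paste(cfg@planted_index, collapse = ","),
              planted_loghr = paste(.fmtNum(cfg@planted_loghr),
                                    collapse = ","))
    writeLines(paste(names(kv), kv, sep = "\t"), paths[["truth"]])
  }
  invisible(paths)
}

.pipelineStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = c("pipelineError", "gliomaScreenError"))))
}

#' Run the simulate/load -> screen -> stratify pipeline
#'
#' The configuration is an R list (or path to a JSON file with the same
#' structure) with sections:
#' \describe{
#'   \item{simulate}{arguments for [SimulationConfig()] — or instead}
#'   \item{input}{paths \code{clinical}, \code{expression}, optional
#'     \code{methylation}, optional \code{normalize}}
#'   \item{screen}{arguments for [PartitionConfig()], optional
#'     \code{genes}, and optional selection thresholds
#'     \code{fraction_threshold} / \code{p_threshold}}
#'   \item{stratify}{\code{gene} (default: the screen's top gene) and
#'     \code{rule}}
#'   \item{seed}{master seed, used for any section that does not set its
#'     own}
#' }
#' Reports embed the package version, seed and parameters; a rerun with
#' the same configuration is byte-identical.
#'
#' @param config List or JSON file path.
#' @param out Optional directory for TSV reports.
#' @return List with \code{cohort}, \code{screen} (ranked table),
#'   \code{selected}, \code{stratify}, \code{methylation} (or
#'   \code{NULL}), \code{summary}, and \code{parameters}.
#' @export
runPipeline <- function(config, out = NULL) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  if (!is.list(config)) .inputError("config must be a list or a JSON path")
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L

  cohort <- if (!is.null(config$simulate)) {
    .pipelineStage("simulate", {
      args <- config$simulate
      if (is.null(args$seed)) args$seed <- seed
      generateCohort(do.call(SimulationConfig, args))
    })
  } else if (!is.null(config$input)) {
    .pipelineStage("load", {
      inp <- config$input
      if (is.null(inp$clinical) || is.null(inp$expression))
        .inputError("input section needs 'clinical' and 'expression' paths")
      expr <- readExpressionMatrix(inp$expression,
                                   normalize = inp$normalize %||% "none")
      meth <- if (!is.null(inp$methylation))
        readMethylationTable(inp$methylation)
      GliomaCohort(expr, readClinicalTable(inp$clinical), methylation = meth)
    })
  } else {
    .inputError("config needs either a 'simulate' or an 'input' section")
  }

  scr_args <- config$screen %||% list()
  sel_frac <- scr_args$fraction_threshold %||% 0.9
  sel_p <- scr_args$p_threshold %||% 0.05
  genes <- scr_args$genes
  scr_args[c("genes", "fraction_threshold", "p_threshold")] <- NULL
  if (is.null(scr_args$seed)) scr_args$seed <- seed
  if (is.null(scr_args$max_size)) scr_args$max_size <- ncol(cohort)
  pcfg <- do.call(PartitionConfig, scr_args)
  screen <- .pipelineStage("screen", genomeScreen(cohort, pcfg, genes = genes))
  selected <- selectRobust(screen, sel_frac, sel_p)

  st_args <- config$stratify %||% list()
  top_gene <- st_args$gene %||% as.character(screen$gene[1])
  rule <- st_args$rule %||% "median"
  strat <- .pipelineStage("stratify",
                          stratifiedKM(cohort, gene = top_gene, rule = rule))

  meth_res <- NULL
  meth <- methylation(cohort)
  if (!is.null(meth) && top_gene %in% rowData(meth)$gene_id)
    meth_res <- .pipelineStage(
      "methylation", methylationAssociation(cohort, top_gene, rule = rule))

  summary <- .pipelineStage("summarize", cohortSummary(cohort))

  parameters <- list(
    version = as.character(utils::packageVersion("gliomaScreen")),
    seed = seed, screen = metadata(screen),
    stratify = list(gene = top_gene, rule = rule),
    selection = list(fraction_threshold = sel_frac, p_threshold = sel_p),
    n_dropped = metadata(cohort)$n_dropped)

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    hdr <- c(sprintf("gliomaScreen %s", parameters$version),
             sprintf("seed %d", seed),
             sprintf("screen B=%d sizes=[%d,%d] alpha=%g ties=%s seed=%d",
                     pcfg@B, pcfg@min_size, pcfg@max_size, pcfg@alpha,
                     pcfg@ties, pcfg@seed))
    .writeTSV(as.data.frame(screen), file.path(out, "screen.tsv"), hdr)
    strat_df <- data.frame(
      group = names(strat$median_os),
      n = as.integer(strat$n),
      median_os = strat$median_os,
      logrank_chisq = strat$logrank@statistic,
      logrank_p = strat$logrank@p)
    .writeTSV(strat_df, file.path(out, "stratify.tsv"),
              c(hdr, sprintf("gene %s rule %s", top_gene, rule)))
    if (!is.null(meth_res))
      .writeTSV(as.data.frame(meth_res), file.path(out, "methylation.tsv"),
                hdr)
  }

  list(cohort = cohort, screen = screen, selected = selected,
       stratify = strat, methylation = meth_res, summary = summary,
       parameters = parameters)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
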