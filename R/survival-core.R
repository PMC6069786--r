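# From-scratch survival statistics: product-limit estimation, the
# Mantel-Haenszel log-rank test, and Newton-Raphson maximisation of the Cox
# partial likelihood with Efron or Breslow handling of tied event times.
# The `survival` package is deliberately NOT used here; it serves only as
# an independent oracle in the test suite.

.checkSurvival <- function(time, event) {
  if (!length(time)) .inputError("at least one subject is required")
  if (length(event) != length(time))
    .inputError("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0))
    .inputError("survival times must be finite and > 0")
  if (!all(event %in% c(0, 1)))
    .inputError("event indicators must be 0 (censored) or 1 (death)")
  invisible(TRUE)
}

#' Kaplan-Meier product-limit estimate
#'
#' Subjects censored exactly at an event time are counted as at risk at
#' that time (the standard convention). The median is the smallest
#' observed event time at which the estimated survival is <= 0.5, and is
#' \code{NA} (reported as "not reached") when survival never drops that
#' far — including when every subject is censored.
#'
#' @param time Positive survival times (months).
#' @param event 0/1 event indicators (1 = death).
#' @return A \linkS4class{KMEstimate}.
#' @examples
#' km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
#' km@surv   # 2/3, 1/3, 0
#' km@median # 2
#' @export
kmEstimate <- function(time, event) {
  .checkSurvival(time, event)
  dt <- sort(unique(time[event == 1]))
  n_risk <- vapply(dt, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(dt, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(n_event / (n_risk * pmax(n_risk - n_event, 0)))
  se <- surv * sqrt(gw)
  se[surv == 0] <- 0
  med_idx <- which(surv <= 0.5 + 1e-12)
  med <- if (length(med_idx)) dt[med_idx[1]] else NA_real_
  .KMEstimate(time = dt, surv = surv, se = se,
              n_risk = n_risk, n_event = n_event, median = med,
              n = length(time), nevent = as.integer(sum(event)))
}

#' Log-rank test of survival difference between groups
#'
#' Mantel-Haenszel statistic: at each distinct event time the observed
#' per-group event counts are compared with their hypergeometric
#' expectations given the risk sets, and the accumulated
#' observed-minus-expected vector is referenced against the accumulated
#' hypergeometric covariance, giving a chi-square statistic on
#' (groups - 1) degrees of freedom. Invariant under relabelling of the
#' groups.
#'
#' @param time,event As in [kmEstimate()].
#' @param group Group labels (coerced to factor); every level must be
#'   non-empty.
#' @return A \linkS4class{LogRankResult}.
#' @examples
#' # one death in group A at t=1, group B censored later:
#' lr <- logrankTest(c(1, 2), c(1, 0), c("A", "B"))
#' lr@statistic # (1 - 0.5)^2 / 0.25 = 1
#' @export
logrankTest <- function(time, event, group) {
  .checkSurvival(time, event)
  group <- factor(group)
  if (nlevels(group) < 2L)
    .inputError("at least two groups are required")
  if (any(tabulate(group, nlevels(group)) == 0L))
    .inputError("every group must be non-empty")
  if (sum(event) == 0)
    .inputError("at least one event is required")
  K <- nlevels(group)
  dt <- sort(unique(time[event == 1]))
  O <- vapply(seq_len(K), function(k)
    sum(event == 1 & as.integer(group) == k), numeric(1))
  E <- numeric(K)
  V <- matrix(0, K, K)
  gi <- as.integer(group)
  for (t in dt) {
    at_risk <- time >= t
    nk <- vapply(seq_len(K), function(k) sum(at_risk & gi == k), numeric(1))
    n. <- sum(nk)
    d. <- sum(time == t & event == 1)
    E <- E + d. * nk / n.
    if (n. > 1) {
      c0 <- d. * (n. - d.) / (n. - 1)
      V <- V + c0 * (diag(nk / n.) - outer(nk, nk) / n.^2)
    }
  }
  OE <- (O - E)[-K]
  Vr <- V[-K, -K, drop = FALSE]
  if (all(abs(Vr) < 1e-300))
    .inputError("log-rank statistic undefined: zero total variance")
  stat <- tryCatch(drop(t(OE) %*% solve(Vr, OE)),
                   error = function(e)
                     .inputError("log-rank variance matrix is singular"))
  names(O) <- names(E) <- levels(group)
  .LogRankResult(statistic = stat, df = K - 1L,
                 p = stats::pchisq(stat, K - 1L, lower.tail = FALSE),
                 observed = O, expected = E)
}

# ---------------------------------------------------------------------------
# Cox partial likelihood engine
# ---------------------------------------------------------------------------

# Evaluate log partial likelihood, score and observed information at beta.
# prep holds time-sorted data plus tie-group bookkeeping.
.coxEval <- function(beta, prep, ties) {
  X <- prep$X
  n <- nrow(X)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  first <- prep$first
  S0 <- .revcumsum(w)[first]
  wX <- X * w
  S1 <- .revcumsum(wX)[first, , drop = FALSE]
  np <- nrow(prep$pairs)
  S2 <- matrix(0, length(first), np)
  for (q in seq_len(np))
    S2[, q] <- .revcumsum(w * X[, prep$pairs[q, 1L]] *
                              X[, prep$pairs[q, 2L]])[first]

  ev <- prep$ev
  gl <- prep$gl                     # factor: event's tie group, levels egrp
  sum_eta <- drop(rowsum(eta[ev], gl))
  sumX <- rowsum(X[ev, , drop = FALSE], gl)
  d <- prep$d                       # events per event-group
  e_idx <- prep$egrp                # row of S0/S1/S2 per event-group
  S0e <- S0[e_idx]
  S1e <- S1[e_idx, , drop = FALSE]
  S2e <- S2[e_idx, , drop = FALSE]

  ll <- 0
  U <- numeric(p)
  Iflat <- numeric(np)
  pr <- prep$pairs

  single <- if (identical(ties, "breslow")) rep(TRUE, length(d)) else d == 1L
  if (any(single)) {
    ds <- d[single]
    S0s <- S0e[single]
    mus <- S1e[single, , drop = FALSE] / S0s
    ll <- ll + sum(sum_eta[single]) - sum(ds * log(S0s))
    U <- U + colSums(sumX[single, , drop = FALSE]) - colSums(ds * mus)
    for (q in seq_len(np))
      Iflat[q] <- Iflat[q] +
        sum(ds * (S2e[single, q] / S0s - mus[, pr[q, 1L]] * mus[, pr[q, 2L]]))
  }
  if (any(!single)) {
    # Efron correction for tied event times
    s0d <- drop(rowsum(w[ev], gl))
    s1d <- rowsum(wX[ev, , drop = FALSE], gl)
    s2d <- matrix(0, length(d), np)
    for (q in seq_len(np))
      s2d[, q] <- drop(rowsum((w * X[, pr[q, 1L]] * X[, pr[q, 2L]])[ev], gl))
    for (e in which(!single)) {
      dd <- d[e]
      f <- (seq_len(dd) - 1) / dd
      den <- S0e[e] - f * s0d[e]
      ll <- ll + sum_eta[e] - sum(log(den))
      num <- matrix(S1e[e, ], dd, p, byrow = TRUE) - outer(f, s1d[e, ])
      mu_l <- num / den
      U <- U + sumX[e, ] - colSums(mu_l)
      for (q in seq_len(np)) {
        s2_l <- S2e[e, q] - f * s2d[e, q]
        Iflat[q] <- Iflat[q] +
          sum(s2_l / den - mu_l[, pr[q, 1L]] * mu_l[, pr[q, 2L]])
      }
    }
  }
  I <- matrix(0, p, p)
  I[cbind(pr[, 1L], pr[, 2L])] <- Iflat
  I[cbind(pr[, 2L], pr[, 1L])] <- Iflat
  list(ll = ll, U = U, I = I)
}

.coxPrep <- function(time, event, X) {
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  X <- X[ord, , drop = FALSE]
  newg <- !duplicated(time)
  grp <- cumsum(newg)
  first <- which(newg)
  ev <- which(event == 1)
  gev <- grp[ev]
  egrp <- sort(unique(gev))
  d <- as.integer(tabulate(factor(gev, levels = egrp)))
  p <- ncol(X)
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  list(time = time, event = event, X = X, first = first,
       ev = ev, gl = factor(gev, levels = egrp), egrp = egrp, d = d,
       pairs = pairs)
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson maximisation of the Cox log partial likelihood, with the
#' Efron (default) or Breslow correction for tied event times; the two are
#' identical when no event times tie. Convergence is declared when the
#' largest absolute component of the score falls below \code{tol};
#' divergence (a coefficient passing |50|, as with perfect separation of
#' the events by a binary covariate) is flagged via
#' \code{converged = FALSE} rather than silently returning a value.
#' Standard errors come from the inverse observed information at the
#' optimum.
#'
#' @param time,event As in [kmEstimate()]; at least one event is required.
#' @param x Covariate matrix (subjects x covariates) or a single numeric
#'   vector. Covariates must be finite and non-constant. No automatic
#'   standardisation is applied here; the screening and cohort-analysis
#'   wrappers standardise continuous expression to mean 0, SD 1 so hazard
#'   ratios are per 1 SD (recorded in the fit's \code{scale} slot).
#' @param ties \code{"efron"} or \code{"breslow"}.
#' @param init Starting coefficients (default all 0).
#' @param max_iter,tol Newton-Raphson controls.
#' @param scale_note Free-text provenance of the covariate scaling,
#'   propagated into the result.
#' @return A \linkS4class{CoxFit}.
#' @examples
#' set.seed(1)
#' tm <- rexp(60); ev <- rbinom(60, 1, 0.8); x <- rnorm(60)
#' coxFit(tm, ev, x)
#' @export
coxFit <- function(time, event, x, ties = c("efron", "breslow"),
                   init = NULL, max_iter = 50L, tol = 1e-9,
                   scale_note = "") {
  ties <- match.arg(ties)
  .checkSurvival(time, event)
  if (sum(event) < 1) .inputError("at least one event is required")
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  storage.mode(X) <- "double"
  if (nrow(X) != length(time))
    .inputError("covariate rows must match the number of subjects")
  if (any(!is.finite(X))) .inputError("covariates must be finite")
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("x", seq_len(ncol(X)))
  const <- apply(X, 2L, function(v) diff(range(v)) == 0)
  if (any(const))
    .inputError(paste("constant covariate(s):",
                      paste(cn[const], collapse = ", ")))

  prep <- .coxPrep(time, event, X)
  p <- ncol(X)
  beta <- if (is.null(init)) numeric(p) else as.numeric(init)
  e <- .coxEval(beta, prep, ties)
  ll0 <- if (all(beta == 0)) e$ll else .coxEval(numeric(p), prep, ties)$ll
  iter <- 0L
  converged <- FALSE
  diverged <- FALSE
  while (TRUE) {
    step <- tryCatch(solve(e$I, e$U), error = function(err) NULL)
    # a monotone (separating) likelihood keeps the score tiny while the
    # Newton step stays large: require both to vanish before declaring
    # convergence
    if (max(abs(e$U)) < tol &&
        !is.null(step) && max(abs(step)) < 1e-3) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter || diverged) break
    if (is.null(step)) break
    bn <- beta + step
    en <- .coxEval(bn, prep, ties)
    h <- 0L
    while ((!is.finite(en$ll) || en$ll < e$ll - 1e-10) && h < 25L) {
      step <- step / 2
      bn <- beta + step
      en <- .coxEval(bn, prep, ties)
      h <- h + 1L
    }
    beta <- bn
    e <- en
    iter <- iter + 1L
    if (any(abs(beta) > 50)) diverged <- TRUE
  }
  if (diverged) converged <- FALSE
  se <- rep(NA_real_, p)
  if (converged) {
    vi <- tryCatch(solve(e$I), error = function(err) NULL)
    if (is.null(vi)) converged <- FALSE else se <- sqrt(diag(vi))
    # saturated information (perfect separation drives the observed
    # information to 0 faster than the score): the scale-free product
    # se * sd(x) is O(1/sqrt(events)) for any healthy fit
    if (!is.null(vi) &&
        any(se * apply(X, 2L, stats::sd) > 10, na.rm = TRUE))
      converged <- FALSE
  }
  names(beta) <- names(se) <- cn
  .CoxFit(coef = beta, se = se, loglik = e$ll, loglik0 = ll0,
          score = e$U, imat = e$I, iter = iter, converged = converged,
          ties = ties, n = length(time), nevent = as.integer(sum(event)),
          scale = scale_note)
}

#' Score test of a Cox model at the null coefficient vector
#'
#' Evaluates the partial-likelihood score and information at beta = 0 and
#' returns the quadratic-form statistic. For a single binary covariate
#' this is algebraically identical to the Mantel-Haenszel log-rank
#' chi-square on the same grouping (with Breslow tie handling), which the
#' test suite exploits as an internal consistency oracle.
#'
#' @inheritParams coxFit
#' @return A list with \code{statistic}, \code{df} and \code{p}.
#' @export
coxScoreTest <- function(time, event, x, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  .checkSurvival(time, event)
  if (sum(event) < 1) .inputError("at least one event is required")
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  storage.mode(X) <- "double"
  prep <- .coxPrep(time, event, X)
  e <- .coxEval(numeric(ncol(X)), prep, ties)
  stat <- drop(t(e$U) %*% solve(e$I, e$U))
  list(statistic = stat, df = ncol(X),
       p = stats::pchisq(stat, ncol(X), lower.tail = FALSE))
}

#' Wald summary of a converged Cox fit
#'
#' Hazard ratios \code{exp(coef)}, Wald confidence intervals
#' \code{exp(coef +/- z * se)} at the requested level, and two-sided
#' normal p-values.
#'
#' @param fit A converged \linkS4class{CoxFit}.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A data.frame with one row per covariate: \code{term},
#'   \code{coef}, \code{se}, \code{hr}, \code{lower}, \code{upper},
#'   \code{z}, \code{p}.
#' @export
waldSummary <- function(fit, level = 0.95) {
  stopifnot(is(fit, "CoxFit"))
  if (!fit@converged)
    .convergenceError("waldSummary requires a converged fit")
  if (level <= 0 || level >= 1) .inputError("level must lie in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  zstat <- fit@coef / fit@se
  data.frame(term = names(fit@coef),
             coef = unname(fit@coef),
             se = unname(fit@se),
             hr = unname(exp(fit@coef)),
             lower = unname(exp(fit@coef - z * fit@se)),
             upper = unname(exp(fit@coef + z * fit@se)),
             z = unname(zstat),
             p = unname(2 * stats::pnorm(-abs(zstat))),
             row.names = NULL)
}
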