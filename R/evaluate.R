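## Monte-Carlo evaluation of a CAT: stopping-rule sweeps over a simulated
## N(0,1) population, conditional error indices (CBIAS/CMAE/CRMSE/CSEE),
## marginal reliability, item savings, concurrent validity and ROC-based
## predictive validity.

#' Monte-Carlo CAT simulation over a sweep of stopping rules
#'
#' Draws \code{nPersons} true traits from N(0, 1), then evaluates every
#' stopping rule on that same population. Adaptive rules run
#' \code{\link{administerCAT}} per person with a random first item and
#' responses simulated on demand at the person's true theta; the
#' \code{"none"} rule administers the whole bank (scored by full-pattern
#' EAP, which coincides with the adaptive full-bank estimate). Fully
#' reproducible from \code{seed}.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param nPersons number of simulees.
#' @param rules list of stopping rules: \code{"none"} or positive SE
#'   thresholds.
#' @param seed integer seed.
#' @param grid a \linkS4class{QuadratureGrid}.
#' @return A list with \code{trueTheta} and \code{results}: one data.frame
#'   per rule (\code{true_theta}, \code{theta}, \code{se}, \code{n_items},
#'   \code{stop_reason}), named \code{"none"}, \code{"se<=0.3"}, etc.
#' @export
runMCSimulation <- function(bank, nPersons = 1000L,
                            rules = list("none", 0.2, 0.3, 0.4, 0.5),
                            seed = 1L, grid = quadratureGrid()) {
  stopifnot(is(bank, "ItemBank"))
  set.seed(as.integer(seed))
  theta <- rnorm(nPersons)
  ruleName <- function(r)
    if (identical(r, "none")) "none" else sprintf("se<=%g", as.numeric(r))
  results <- list()
  for (ri in seq_along(rules)) {
    r <- rules[[ri]]
    set.seed(as.integer(seed) + 10007L * ri)
    if (identical(r, "none")) {
      resp <- simulateResponses(bank, theta)
      sc <- eapScore(bank, resp, grid)
      df <- data.frame(true_theta = theta, theta = sc$theta, se = sc$se,
                       n_items = nItems(bank),
                       stop_reason = "none_rule_complete",
                       stringsAsFactors = FALSE)
    } else {
      cfg <- catConfig(stop = as.numeric(r), grid = grid)
      df <- data.frame(true_theta = theta, theta = NA_real_,
                       se = NA_real_, n_items = NA_integer_,
                       stop_reason = NA_character_,
                       stringsAsFactors = FALSE)
      for (p in seq_len(nPersons)) {
        rec <- administerCAT(bank, simulatedResponder(theta[p]), cfg)
        df$theta[p] <- rec@estimate@theta
        df$se[p] <- rec@estimate@se
        df$n_items[p] <- rec@estimate@nItemsUsed
        df$stop_reason[p] <- rec@stopReason
      }
    }
    results[[ruleName(r)]] <- df
  }
  list(trueTheta = theta, results = results)
}

#' Conditional and overall error indices
#'
#' CBIAS (mean estimation error), CMAE (mean absolute error), CRMSE (root
#' mean square error) and CSEE (mean reported standard error), overall and
#' conditioned on true-theta bins. Overall values are person-level means
#' over all simulees (not means of bin means, which would over-weight the
#' sparse extremes). Empty bins are reported as NA.
#'
#' @param trueThetas,estimates,ses equal-length numeric vectors.
#' @param binEdges bin edges on the theta axis (default width 0.5 on
#'   [-4, 4]).
#' @return List with \code{overall} (named: cbias, cmae, crmse, csee, n)
#'   and \code{byBin} (data.frame with bin bounds and the four indices).
#' @export
conditionalStats <- function(trueThetas, estimates, ses,
                             binEdges = seq(-4, 4, by = 0.5)) {
  n <- length(trueThetas)
  stopifnot(length(estimates) == n, length(ses) == n, n >= 1)
  err <- estimates - trueThetas
  overall <- c(cbias = mean(err), cmae = mean(abs(err)),
               crmse = sqrt(mean(err^2)), csee = mean(ses), n = n)
  bin <- cut(trueThetas, binEdges, include.lowest = TRUE)
  byBin <- data.frame(
    lower = head(binEdges, -1), upper = binEdges[-1],
    n = as.integer(table(bin)),
    cbias = as.numeric(tapply(err, bin, mean)),
    cmae = as.numeric(tapply(abs(err), bin, mean)),
    crmse = sqrt(as.numeric(tapply(err^2, bin, mean))),
    csee = as.numeric(tapply(ses, bin, mean)))
  list(overall = overall, byBin = byBin)
}

#' Marginal reliability from per-person standard errors
#'
#' The mean SE across persons is squared and subtracted from one:
#' \eqn{MR = 1 - \bar{SE}^2} with \eqn{\bar{SE} = \sum_i SE(\theta_i)/N}.
#'
#' @param ses positive numeric vector of per-person SEs (posterior SDs).
#' @return Marginal reliability (a scalar below 1).
#' @examples
#' marginalReliability(rep(0.293, 10))  # 0.914
#' @export
marginalReliability <- function(ses) {
  stopifnot(length(ses) >= 1, all(ses >= 0))
  1 - mean(ses)^2
}

#' Item savings, reliability and cross-rule agreement
#'
#' Summarizes a stopping-rule sweep evaluated on one shared population:
#' mean and SD of items used, mean SE, marginal reliability, Pearson
#' correlation of each rule's estimates with the full-bank (reference)
#' estimates, and the item-savings percentage
#' \code{100 * (1 - meanItems / bankSize)}.
#'
#' @param results named list of per-rule data.frames as produced by
#'   \code{\link{runMCSimulation}} (columns \code{theta}, \code{se},
#'   \code{n_items}; all rules over the same persons).
#' @param bankSize number of items in the bank.
#' @param reference name of the reference rule (default \code{"none"}).
#' @return data.frame with one row per rule: \code{rule},
#'   \code{mean_items}, \code{sd_items}, \code{mean_se}, \code{mr},
#'   \code{r}, \code{savings_pct}.
#' @export
savingsAndCorrelations <- function(results, bankSize,
                                   reference = "none") {
  stopifnot(reference %in% names(results))
  ns <- vapply(results, nrow, integer(1))
  if (length(unique(ns)) != 1)
    stop("all rules must be evaluated on the same persons")
  ref <- results[[reference]]$theta
  out <- do.call(rbind, lapply(names(results), function(nm) {
    d <- results[[nm]]
    data.frame(rule = nm,
               mean_items = mean(d$n_items),
               sd_items = sd(d$n_items),
               mean_se = mean(d$se),
               mr = marginalReliability(d$se),
               r = cor(d$theta, ref),
               savings_pct = 100 * (1 - mean(d$n_items) / bankSize),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Concurrent validity against source-scale sum scores
#'
#' Pearson correlation (with two-tailed p) between trait estimates and the
#' sum score of each source scale's items in the response matrix.
#'
#' @param thetaHats numeric vector of estimates, one per person.
#' @param responses a \linkS4class{ResponseMatrix}.
#' @param scaleMap optional named character vector mapping item id to
#'   scale; defaults to the \code{source_scale} item metadata when present,
#'   otherwise the id prefix before \code{"-"}.
#' @return data.frame per scale: \code{scale}, \code{n_items}, \code{r},
#'   \code{p}. A zero-variance sum score yields NA with a warning.
#' @export
concurrentValidity <- function(thetaHats, responses, scaleMap = NULL) {
  stopifnot(is(responses, "ResponseMatrix"))
  X <- scoreMatrix(responses)
  stopifnot(length(thetaHats) == nrow(X))
  if (is.null(scaleMap)) {
    meta <- as.data.frame(SummarizedExperiment::rowData(responses))
    scaleMap <- if ("source_scale" %in% names(meta))
      stats::setNames(meta$source_scale, rownames(meta))
    else stats::setNames(sub("-.*$", "", colnames(X)), colnames(X))
  }
  scales <- unique(scaleMap[colnames(X)])
  out <- do.call(rbind, lapply(scales, function(scl) {
    cols <- colnames(X)[scaleMap[colnames(X)] == scl]
    s <- rowSums(X[, cols, drop = FALSE])
    if (sd(s) == 0) {
      warning("zero-variance sum score for scale ", scl)
      return(data.frame(scale = scl, n_items = length(cols),
                        r = NA_real_, p = NA_real_))
    }
    ct <- cor.test(thetaHats, s)
    data.frame(scale = scl, n_items = length(cols),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' ROC-based predictive validity
#'
#' AUC via the rank (Mann-Whitney) formulation with half-credit for ties,
#' equal to the proportion of (case, control) pairs in which the case
#' outranks the control. The 95% CI uses the Hanley-McNeil variance by
#' default (DeLong's empirical-placement variance is available). The
#' optimal cut-off maximizes the Youden index (sensitivity + specificity -
#' 1) over midpoints between consecutive sorted unique predictor values;
#' exact ties in the Youden index resolve toward the higher cut-off
#' (higher specificity).
#'
#' @param thetaHats numeric predictor (higher = more likely case).
#' @param labels logical (or two-level) case labels; both classes must be
#'   present.
#' @param ciMethod \code{"hanley"} or \code{"delong"}.
#' @return List: \code{auc}, \code{ci} (length 2), \code{cutoff},
#'   \code{sensitivity}, \code{specificity}, \code{youden},
#'   \code{nCases}, \code{nControls}.
#' @export
rocPredictiveValidity <- function(thetaHats, labels,
                                  ciMethod = c("hanley", "delong")) {
  ciMethod <- match.arg(ciMethod)
  if (is.factor(labels) || is.character(labels))
    labels <- labels == sort(unique(as.character(labels)))[2L]
  labels <- as.logical(labels)
  stopifnot(length(thetaHats) == length(labels), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present (cases: ", n1,
         ", controls: ", n0, ")")
  rk <- rank(thetaHats)  # midranks: half-credit for ties
  auc <- (sum(rk[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (ciMethod == "hanley") {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
            (n0 - 1) * (q2 - auc^2)) / (n1 * n0)
  } else {
    x <- thetaHats[labels]; y <- thetaHats[!labels]
    v10 <- vapply(x, function(xi)
      (sum(xi > y) + 0.5 * sum(xi == y)) / n0, numeric(1))
    v01 <- vapply(y, function(yi)
      (sum(x > yi) + 0.5 * sum(x == yi)) / n1, numeric(1))
    v <- var(v10) / n1 + var(v01) / n0
  }
  hw <- 1.959963984540054 * sqrt(max(v, 0))
  ci <- c(max(0, auc - hw), min(1, auc + hw))
  ## Youden scan over midpoints (classify positive when thetaHat >= cut)
  u <- sort(unique(thetaHats))
  cuts <- if (length(u) > 1) (head(u, -1) + u[-1]) / 2 else u
  cuts <- c(u[1L] - 1, cuts, u[length(u)] + 1)
  best <- NULL
  for (ct in cuts) {
    sens <- sum(thetaHats >= ct & labels) / n1
    spec <- sum(thetaHats < ct & !labels) / n0
    yi <- sens + spec - 1
    if (is.null(best) || yi > best$youden + 1e-12 ||
        (abs(yi - best$youden) <= 1e-12 && ct > best$cutoff))
      best <- list(cutoff = ct, sensitivity = sens, specificity = spec,
                   youden = yi)
  }
  c(list(auc = auc, ci = ci), best,
    list(nCases = n1, nControls = n0, ciMethod = ciMethod))
}

#' Scale-based diagnostic rules
#'
#' \code{diagnosticRule} describes a classification rule over raw scale
#' scores: a \code{"sum"} rule labels a person positive when the sum of the
#' listed items strictly exceeds \code{sumCut} (e.g. the 20-item IAT rule,
#' sum > 39); a \code{"count"} rule labels positive when at least
#' \code{countCut} of the listed items score \code{scoreCut} or higher
#' (e.g. the GAS rule: at least 4 of the 7 diagnostic items scoring 4 or
#' 5).
#'
#' @param type \code{"sum"} or \code{"count"}.
#' @param items character vector of item ids the rule reads.
#' @param sumCut strict lower bound for the sum rule.
#' @param scoreCut minimum qualifying score for the count rule.
#' @param countCut minimum number of qualifying items for the count rule.
#' @return A rule object for \code{\link{applyDiagnosticRule}}.
#' @export
diagnosticRule <- function(type = c("sum", "count"), items,
                           sumCut = 39, scoreCut = 4, countCut = 4) {
  type <- match.arg(type)
  stopifnot(length(items) >= 1)
  list(type = type, items = as.character(items), sumCut = sumCut,
       scoreCut = scoreCut, countCut = countCut)
}

#' @param responses a \linkS4class{ResponseMatrix}.
#' @param rule a \code{\link{diagnosticRule}}.
#' @return \code{applyDiagnosticRule}: logical vector, one label per
#'   person.
#' @rdname diagnosticRule
#' @export
applyDiagnosticRule <- function(responses, rule) {
  stopifnot(is(responses, "ResponseMatrix"))
  X <- scoreMatrix(responses)
  miss <- setdiff(rule$items, colnames(X))
  if (length(miss) > 0)
    stop("rule items missing from responses: ",
         paste(miss, collapse = ", "))
  S <- X[, rule$items, drop = FALSE]
  if (rule$type == "sum") rowSums(S) > rule$sumCut
  else rowSums(S >= rule$scoreCut) >= rule$countCut
}
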