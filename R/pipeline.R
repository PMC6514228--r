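## The iterated item-bank construction pipeline: unidimensionality -> GRM
## calibration -> local independence (Q3) -> monotonicity (Mokken) ->
## item fit / DIF / discrimination, repeated until a full pass excludes
## nothing.

#' Run the six-step item-bank construction pipeline
#'
#' Steps, in order: (1) unidimensionality screen (items loading below the
#' cut are dropped); GRM recalibration; (3) local independence: of each
#' flagged Q3 pair the member with the lower item scalability H_j is
#' dropped (ties: lower discrimination, then lexicographically smaller id);
#' (4) monotonicity: items with H_j below the cut are dropped; (5/6) item
#' fit (S-X2), DIF (per grouping variable) and low discrimination, dropped
#' together. After any exclusion wave the pipeline recalibrates and starts
#' the pass again; it terminates when a complete pass excludes nothing, so
#' re-running it on its own surviving bank is a no-op. When an item trips
#' several step-5 screens its reason code follows the step order (item
#' fit, then DIF, then discrimination).
#'
#' @param responses a \linkS4class{ResponseMatrix} of the candidate pool.
#' @param groups character vector of two-level person covariates to test
#'   for DIF (empty: DIF skipped).
#' @param thresholds a \code{\link{qcThresholds}} list.
#' @param grid a \linkS4class{QuadratureGrid}.
#' @param maxIterations hard cap on exclusion waves.
#' @param minExpected minimum expected cell count for S-X2.
#' @param verbose log each wave's exclusions to the console.
#' @return A list of class \code{qcReport}: \code{exclusions} (data.frame
#'   \code{item_id}, \code{reason}, \code{wave}, \code{statistic}),
#'   \code{surviving} (item ids), \code{bank} (final calibrated
#'   \linkS4class{ItemBank}), \code{iterations}, \code{thresholds},
#'   \code{stepLog}.
#' @export
runQCPipeline <- function(responses, groups = character(0),
                          thresholds = qcThresholds(),
                          grid = quadratureGrid(), maxIterations = 25L,
                          minExpected = 1, verbose = FALSE) {
  stopifnot(is(responses, "ResponseMatrix"))
  allIds <- itemIds(responses)
  current <- responses
  exclusions <- data.frame(item_id = character(0), reason = character(0),
                           wave = integer(0), statistic = numeric(0),
                           stringsAsFactors = FALSE)
  stepLog <- list()
  wave <- 0L
  bank <- NULL
  note <- function(...) if (verbose) message(sprintf(...))
  drop <- function(ids, reason, stat) {
    exclusions <<- rbind(exclusions, data.frame(
      item_id = ids, reason = reason, wave = wave,
      statistic = stat, stringsAsFactors = FALSE))
    keep <- setdiff(itemIds(current), ids)
    if (length(keep) < 3)
      stop("no bank survives: fewer than 3 items remain after exclusions")
    current <<- current[keep, ]
    note("wave %d: excluded %s (%s)", wave, paste(ids, collapse = ", "),
         reason)
  }

  repeat {
    wave <- wave + 1L
    if (wave > maxIterations)
      stop("pipeline did not reach a fixed point in ", maxIterations,
           " waves")
    ## Step 1: unidimensionality
    efa <- efaScreen(current, thresholds)
    stepLog[[length(stepLog) + 1L]] <- list(wave = wave, step = "efa",
                                            result = efa)
    if (length(efa$excluded) > 0) {
      drop(efa$excluded, "unidimensionality",
           efa$loadings[efa$excluded])
      next
    }
    ## calibrate
    cal <- calibrateGRM(current, grid)
    bank <- cal$bank
    ## Step 3: local independence
    q3 <- q3Matrix(current, bank, grid, thresholds)
    stepLog[[length(stepLog) + 1L]] <- list(wave = wave, step = "q3",
                                            result = q3$flagged)
    mok <- mokkenScalability(current, thresholds)
    if (nrow(q3$flagged) > 0) {
      a <- discrimination(bank)
      dropped <- character(0); stats <- numeric(0)
      for (r in seq_len(nrow(q3$flagged))) {
        pair <- c(q3$flagged$item_i[r], q3$flagged$item_j[r])
        if (any(pair %in% dropped)) next
        hj <- mok$Hj[pair]; aj <- a[pair]
        o <- order(hj, aj, pair)       # lower H, then lower a, then id
        dropped <- c(dropped, pair[o[1L]])
        stats <- c(stats, q3$flagged$q3[r])
      }
      drop(dropped, "local_dependence", stats)
      next
    }
    ## Step 4: monotonicity
    stepLog[[length(stepLog) + 1L]] <- list(wave = wave, step = "mokken",
                                            result = mok[c("H", "Hj")])
    if (length(mok$excluded) > 0) {
      drop(mok$excluded, "monotonicity", mok$Hj[mok$excluded])
      next
    }
    ## Steps 5/6: item fit, DIF, discrimination
    fit <- sx2ItemFit(current, bank, grid, minExpected, thresholds)
    theta <- eapScore(bank, current, grid)$theta
    difTabs <- lapply(groups, function(gv)
      difOrdinalLogistic(current, gv, bank, grid, thresholds,
                         theta = theta))
    names(difTabs) <- groups
    lowA <- discriminationFilter(bank, thresholds)
    stepLog[[length(stepLog) + 1L]] <- list(wave = wave, step = "step5",
                                            fit = fit, dif = difTabs,
                                            lowA = lowA)
    fitDrop <- fit$item_id[fit$flagged %in% TRUE]
    difDrop <- unique(unlist(lapply(difTabs, function(d)
      d$item_id[d$flagged %in% TRUE])))
    ids <- character(0); reasons <- character(0); stats <- numeric(0)
    for (id in fitDrop) {
      ids <- c(ids, id); reasons <- c(reasons, "item_fit")
      stats <- c(stats, fit$p[fit$item_id == id])
    }
    for (id in setdiff(difDrop, ids)) {
      ids <- c(ids, id); reasons <- c(reasons, "dif")
      stats <- c(stats, max(vapply(difTabs, function(d) {
        v <- d$deltaR2[d$item_id == id]
        if (length(v) == 0 || is.na(v)) -Inf else v
      }, numeric(1))))
    }
    for (id in setdiff(lowA, ids)) {
      ids <- c(ids, id); reasons <- c(reasons, "discrimination")
      stats <- c(stats, discrimination(bank)[id])
    }
    if (length(ids) > 0) {
      for (k in seq_along(ids)) {
        exclusions <- rbind(exclusions, data.frame(
          item_id = ids[k], reason = reasons[k], wave = wave,
          statistic = stats[k], stringsAsFactors = FALSE))
      }
      keep <- setdiff(itemIds(current), ids)
      if (length(keep) < 3)
        stop("no bank survives: fewer than 3 items remain")
      current <- current[keep, ]
      note("wave %d: excluded %s", wave, paste(ids, collapse = ", "))
      next
    }
    break  # full pass with no exclusions: fixed point reached
  }
  out <- list(exclusions = exclusions, surviving = itemIds(current),
              bank = bank, iterations = wave, thresholds = thresholds,
              stepLog = stepLog)
  class(out) <- "qcReport"
  out
}

#' @export
print.qcReport <- function(x, ...) {
  cat("Item-bank QC report:", length(x$surviving), "surviving item(s),",
      nrow(x$exclusions), "excluded in", x$iterations, "wave(s)\n")
  if (nrow(x$exclusions) > 0) {
    tab <- table(x$exclusions$reason)
    for (r in names(tab))
      cat(sprintf("  %s: %d (%s)\n", r, tab[[r]],
                  paste(x$exclusions$item_id[x$exclusions$reason == r],
                        collapse = ", ")))
  }
  invisible(x)
}

#' Write a QC report to JSON
#'
#' @param report a \code{qcReport} from \code{\link{runQCPipeline}}.
#' @param path output path.
#' @export
writeQCReport <- function(report, path) {
  stopifnot(inherits(report, "qcReport"))
  jsonlite::write_json(list(
    surviving = report$surviving,
    exclusions = report$exclusions,
    iterations = report$iterations,
    thresholds = report$thresholds), path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
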