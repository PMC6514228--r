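## Adaptive administration: random (or fixed) first item, maximum-
## information selection at the current EAP estimate, EAP update after each
## response, SE-threshold stopping.

#' Build a CAT configuration
#'
#' @param stop stopping rule: the string \code{"none"} (administer the whole
#'   bank) or a positive SE threshold such as \code{0.3} (stop once the
#'   posterior-SD standard error falls to or below the threshold).
#' @param initialItem \code{"random"} (uniform over the bank, seeded) or a
#'   fixed item id.
#' @param grid a \linkS4class{QuadratureGrid}.
#' @param maxItems optional maximum test length (default: bank exhaustion
#'   only).
#' @param seed integer seed, or \code{NA} to use the current RNG state.
#' @return A \linkS4class{CATConfig}.
#' @export
catConfig <- function(stop = "none", initialItem = "random",
                      grid = quadratureGrid(), maxItems = Inf,
                      seed = NA_integer_) {
  if (identical(stop, "none")) {
    rule <- "none"; thr <- NA_real_
  } else {
    thr <- as.numeric(stop)
    if (length(thr) != 1L || is.na(thr) || thr <= 0)
      stop("stop must be \"none\" or a positive SE threshold")
    rule <- "se_threshold"
  }
  new("CATConfig", stoppingRule = rule, seThreshold = thr,
      initialItem = as.character(initialItem), maxItems = maxItems,
      grid = grid, seed = as.integer(seed))
}

setMethod("show", "CATConfig", function(object) {
  rule <- if (object@stoppingRule == "none") "none (full bank)"
          else sprintf("SE <= %g", object@seThreshold)
  cat("CATConfig: EAP estimator, MIC selection, stopping rule", rule, "\n")
  cat("  initial item:", object@initialItem,
      "| seed:", object@seed, "\n")
})

#' Select the first CAT item
#'
#' Under \code{initialItem = "random"} the first item is drawn uniformly
#' from the bank (to spread item exposure); a fixed item id is returned
#' as-is after checking membership.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param config a \linkS4class{CATConfig}; when its \code{seed} slot is not
#'   \code{NA}, the RNG is seeded first, making the draw reproducible.
#' @return An item id.
#' @export
selectInitialItem <- function(bank, config) {
  stopifnot(is(bank, "ItemBank"), is(config, "CATConfig"))
  if (config@initialItem == "random") {
    if (!is.na(config@seed)) set.seed(config@seed)
    itemIds(bank)[sample.int(nItems(bank), 1L)]
  } else {
    if (!(config@initialItem %in% itemIds(bank)))
      stop("configured initial item not in bank: ", config@initialItem)
    config@initialItem
  }
}

#' Maximum-information item selection
#'
#' Returns the unadministered item with the largest Fisher information at
#' the current trait estimate; exact ties are broken toward the
#' lexicographically smallest item id.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param administered character vector of already-administered item ids.
#' @param thetaHat current trait estimate.
#' @return An item id.
#' @export
selectNextItemMIC <- function(bank, administered, thetaHat) {
  stopifnot(is(bank, "ItemBank"))
  remaining <- setdiff(itemIds(bank), administered)
  if (length(remaining) == 0)
    stop("bank exhausted: no unadministered items remain")
  idx <- .itemIndex(bank, remaining)
  par <- .bankPar(bank)
  info <- .infoAt(par$a[idx], par$b[idx, , drop = FALSE], thetaHat)
  best <- remaining[info == max(info)]
  sort(best)[1L]
}

## internal responder closure: returns function(itemId) -> score 1..5
.makeResponder <- function(bank, responder) {
  if (identical(responder$mode, "simulated")) {
    theta <- responder$theta
    par <- .bankPar(bank)
    function(itemId) {
      i <- .itemIndex(bank, itemId)
      ps <- plogis(par$a[i] * (theta - par$b[i, ]))
      1L + sum(runif(1) < ps)
    }
  } else if (identical(responder$mode, "observed")) {
    v <- responder$scores
    function(itemId) {
      if (!(itemId %in% names(v)))
        stop("observed response vector is missing item ", itemId)
      as.integer(v[[itemId]])
    }
  } else stop("responder$mode must be 'simulated' or 'observed'")
}

#' Responder sources for adaptive administration
#'
#' \code{simulatedResponder} answers each selected item by sampling from the
#' GRM category probabilities at a known true theta;
#' \code{observedResponder} answers from a fixed, fully observed response
#' vector (real-data mode), which must cover every item that may be
#' selected.
#'
#' @param theta true latent-trait value of the simulated person.
#' @return A responder specification for \code{\link{administerCAT}}.
#' @export
simulatedResponder <- function(theta) {
  stopifnot(length(theta) == 1L, is.finite(theta))
  list(mode = "simulated", theta = theta)
}

#' @param scores named integer vector (or single-person
#'   \linkS4class{ResponseMatrix}) of scores 1..5 covering the bank.
#' @rdname simulatedResponder
#' @export
observedResponder <- function(scores) {
  if (is(scores, "ResponseMatrix")) {
    stopifnot(nPersons(scores) == 1L)
    v <- scoreMatrix(scores)[1L, ]
  } else v <- scores
  stopifnot(!is.null(names(v)), all(v %in% 1:5))
  list(mode = "observed", scores = v)
}

#' Run one adaptive administration
#'
#' The loop is: administer the current item, update the EAP estimate, check
#' the stopping rule, then select the next item by maximum information at
#' the updated estimate. Under the \code{"none"} rule the full bank is
#' administered; under an SE threshold the test stops the first time the
#' posterior SD falls to or below the threshold (minimum one item), or when
#' the bank is exhausted. The final estimate of a full-bank run equals
#' non-adaptive EAP scoring of the same responses bit-for-bit.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param responder a \code{\link{simulatedResponder}} or
#'   \code{\link{observedResponder}}.
#' @param config a \linkS4class{CATConfig}. When \code{config@seed} is not
#'   \code{NA} the RNG is seeded once at the start (covering the random
#'   initial item and simulated responses).
#' @return A \linkS4class{CATRecord}.
#' @export
administerCAT <- function(bank, responder, config = catConfig()) {
  stopifnot(is(bank, "ItemBank"), is(config, "CATConfig"))
  validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  grid <- config@grid
  lpArr <- .logProbArray(bank, grid)
  par <- .bankPar(bank)
  respond <- .makeResponder(bank, responder)
  J <- nItems(bank)

  if (config@initialItem == "random")
    item <- itemIds(bank)[sample.int(J, 1L)]
  else {
    if (!(config@initialItem %in% itemIds(bank)))
      stop("configured initial item not in bank: ", config@initialItem)
    item <- config@initialItem
  }

  idx <- integer(0); scores <- integer(0); ids <- character(0)
  stepTheta <- numeric(0); stepSE <- numeric(0)
  stopReason <- NA_character_
  repeat {
    sc <- respond(item)
    ids <- c(ids, item)
    idx <- c(idx, .itemIndex(bank, item))
    scores <- c(scores, sc)
    est <- .eapCore(idx, scores, lpArr, grid)
    stepTheta <- c(stepTheta, est$theta)
    stepSE <- c(stepSE, est$se)
    if (config@stoppingRule == "se_threshold" &&
        est$se <= config@seThreshold) {
      stopReason <- "se_reached"; break
    }
    if (length(idx) == J) {
      stopReason <- if (config@stoppingRule == "none")
        "none_rule_complete" else "bank_exhausted"
      break
    }
    if (length(idx) >= config@maxItems) {
      stopReason <- "max_items"; break
    }
    remaining <- setdiff(seq_len(J), idx)
    info <- .infoAt(par$a[remaining], par$b[remaining, , drop = FALSE],
                    est$theta)
    best <- remaining[info == max(info)]
    item <- sort(itemIds(bank)[best])[1L]
  }
  estimate <- new("ThetaEstimate", theta = est$theta, se = est$se,
                  nItemsUsed = length(ids), trace = ids)
  steps <- data.frame(item_id = ids, response = scores,
                      theta = stepTheta, se = stepSE,
                      stringsAsFactors = FALSE)
  new("CATRecord", estimate = estimate, steps = steps,
      stopReason = stopReason)
}

setMethod("show", "ThetaEstimate", function(object) {
  cat(sprintf("ThetaEstimate: theta = %.4f (SE %.4f) from %d item(s)\n",
              object@theta, object@se, object@nItemsUsed))
})

setMethod("show", "CATRecord", function(object) {
  est <- object@estimate
  cat(sprintf(
    "CATRecord: %d item(s), final theta %.4f (SE %.4f), stop: %s\n",
    est@nItemsUsed, est@theta, est@se, object@stopReason))
})
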