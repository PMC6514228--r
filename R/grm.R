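## Graded response model core: boundary/category probabilities, Fisher
## information, likelihoods, quadrature. Category file coding is 1..5
## throughout the user-facing API; the internal 0..4 coding appears only in
## summed-score recursions.

#' Quadrature grid for posterior integration
#'
#' Equally spaced nodes with standard-normal prior weights renormalized to
#' sum to 1; the two endpoint nodes carry half weight (composite trapezoid
#' rule), which removes the O(h) boundary bias that full endpoint weights
#' introduce for diffuse posteriors. The default (81 nodes on [-4, 4])
#' matches the N(0, 1) trait prior used for EAP scoring and calibration.
#'
#' @param n number of nodes.
#' @param range numeric length-2, node range on the theta scale.
#' @return A \linkS4class{QuadratureGrid}.
#' @export
quadratureGrid <- function(n = 81L, range = c(-4, 4)) {
  stopifnot(n >= 2, length(range) == 2, range[1] < range[2])
  nodes <- seq(range[1], range[2], length.out = n)
  w <- dnorm(nodes)
  w[c(1L, n)] <- w[c(1L, n)] / 2
  new("QuadratureGrid", nodes = nodes, weights = w / sum(w))
}

setMethod("show", "QuadratureGrid", function(object) {
  cat(sprintf("QuadratureGrid: %d nodes on [%g, %g], N(0,1) prior\n",
              length(object@nodes), min(object@nodes), max(object@nodes)))
})

## internal: bank parameters as plain vectors/matrices
.bankPar <- function(bank) {
  list(a = bank@items$a,
       b = as.matrix(bank@items[, c("b1", "b2", "b3", "b4")]),
       ids = bank@items$item_id)
}

## internal: resolve an item reference (id or position) to a row index
.itemIndex <- function(bank, item) {
  if (is.character(item)) {
    i <- match(item, bank@items$item_id)
    if (anyNA(i)) stop("unknown item_id: ",
                       paste(item[is.na(i)], collapse = ", "))
    i
  } else as.integer(item)
}

## internal: cumulative (boundary) probabilities P(X >= k+1), J x 4,
## at scalar theta
.cumProbs <- function(a, b, theta) {
  plogis(a * (theta - b))  # recycles a over the 4 columns of b
}

## internal: category probabilities (J x 5) at scalar theta
.catProbs <- function(a, b, theta) {
  ps <- .cumProbs(a, b, theta)
  cbind(1 - ps[, 1L], ps[, 1L] - ps[, 2L], ps[, 2L] - ps[, 3L],
        ps[, 3L] - ps[, 4L], ps[, 4L], deparse.level = 0)
}

## internal: log category probability array, J x 5 x Q over grid nodes
.logProbArray <- function(bank, grid) {
  par <- .bankPar(bank)
  J <- length(par$a); Q <- length(grid@nodes)
  arr <- array(NA_real_, dim = c(J, 5L, Q))
  for (q in seq_len(Q))
    arr[, , q] <- log(pmax(.catProbs(par$a, par$b, grid@nodes[q]), 1e-300))
  arr
}

#' GRM boundary probability
#'
#' Probability of responding in category k+1 or above,
#' \eqn{P^*_k(\theta) = 1 / (1 + \exp(-a(\theta - b_k)))}.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param item item id (character) or position (integer).
#' @param theta latent-trait value(s).
#' @param k threshold index, 1..4.
#' @return Probability (vectorized over \code{theta}).
#' @export
boundaryProb <- function(bank, item, theta, k) {
  stopifnot(is(bank, "ItemBank"))
  if (length(k) != 1L || !(k %in% 1:4))
    stop("threshold index k must be in 1..4")
  i <- .itemIndex(bank, item)
  par <- .bankPar(bank)
  unname(plogis(par$a[i] * (theta - par$b[i, k])))
}

#' GRM category probabilities
#'
#' Probabilities of the five ordered response categories,
#' \eqn{P_c = P^*_{c-1} - P^*_c} with \eqn{P^*_0 = 1} and \eqn{P^*_5 = 0}.
#' They are non-negative and sum to one at any theta.
#'
#' @inheritParams boundaryProb
#' @return For scalar \code{theta} a length-5 probability vector; for vector
#'   \code{theta} a \code{length(theta) x 5} matrix.
#' @export
categoryProbs <- function(bank, item, theta) {
  stopifnot(is(bank, "ItemBank"))
  i <- .itemIndex(bank, item)
  a <- bank@items$a[i]
  b <- as.numeric(bank@items[i, c("b1", "b2", "b3", "b4")])
  out <- t(vapply(theta, function(th) {
    ps <- plogis(a * (th - b))
    c(1 - ps[1], ps[1] - ps[2], ps[2] - ps[3], ps[3] - ps[4], ps[4])
  }, numeric(5)))
  colnames(out) <- paste0("cat", 1:5)
  if (length(theta) == 1L) out[1L, ] else out
}

## internal: Fisher information for all bank items at scalar theta.
## Samejima: I_j = sum_c (P'_c)^2 / P_c with
## P'_c = a [ P*_{c-1}(1-P*_{c-1}) - P*_c(1-P*_c) ], P*_0 = 1, P*_5 = 0.
.infoAt <- function(a, b, theta) {
  ps <- .cumProbs(a, b, theta)            # J x 4
  qs <- ps * (1 - ps)                     # P*(1-P*)
  qpad <- cbind(0, qs, 0, deparse.level = 0)  # J x 6 with Q_0 = Q_5 = 0
  dP <- a * (qpad[, 1:5, drop = FALSE] - qpad[, 2:6, drop = FALSE])
  P <- .catProbs(a, b, theta)
  rowSums(dP * dP / pmax(P, 1e-300))
}

#' GRM item information
#'
#' Fisher information of one item at the given theta value(s)
#' (Samejima's formula for the graded response model).
#'
#' @inheritParams boundaryProb
#' @return Information values, vectorized over \code{theta}.
#' @export
itemInformation <- function(bank, item, theta) {
  stopifnot(is(bank, "ItemBank"))
  i <- .itemIndex(bank, item)
  par <- .bankPar(bank)
  vapply(theta, function(th)
    .infoAt(par$a[i], par$b[i, , drop = FALSE], th), numeric(1))
}

#' Test information for a set of items
#'
#' Fisher information is additive over locally independent items, so test
#' information is the sum of item informations.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param theta latent-trait value(s).
#' @param items optional subset of item ids/positions (default: all items).
#' @return Information values, vectorized over \code{theta}.
#' @export
testInformation <- function(bank, theta, items = NULL) {
  stopifnot(is(bank, "ItemBank"))
  if (!is.null(items)) bank <- bank[.itemIndex(bank, items)]
  if (nItems(bank) == 0) stop("empty item subset")
  par <- .bankPar(bank)
  vapply(theta, function(th) sum(.infoAt(par$a, par$b, th)), numeric(1))
}

#' Log-likelihood of a response pattern
#'
#' Sum of log category probabilities over the items of the pattern;
#' invariant to item order (terms are accumulated in bank order).
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param itemIds character, administered item ids.
#' @param scores integer scores 1..5, same length as \code{itemIds}.
#' @param theta latent-trait value(s).
#' @return Log-likelihood, vectorized over \code{theta}; 0 for an empty
#'   pattern.
#' @export
logLikelihood <- function(bank, itemIds, scores, theta) {
  stopifnot(is(bank, "ItemBank"), length(itemIds) == length(scores))
  if (length(itemIds) == 0) return(rep(0, length(theta)))
  if (any(scores < 1 | scores > 5)) stop("scores must be in 1..5")
  idx <- .itemIndex(bank, itemIds)
  o <- order(idx)  # canonical accumulation order
  idx <- idx[o]; sc <- as.integer(scores)[o]
  par <- .bankPar(bank)
  vapply(theta, function(th) {
    P <- .catProbs(par$a[idx], par$b[idx, , drop = FALSE], th)
    sum(log(pmax(P[cbind(seq_along(idx), sc)], 1e-300)))
  }, numeric(1))
}

#' IRT model-fit indices
#'
#' \code{AIC = -2LL + 2p} and \code{BIC = -2LL + p log(N)} from a fitted
#' model's deviance, parameter count and sample size.
#'
#' @param neg2LL deviance (-2 log-likelihood).
#' @param nParams number of free parameters (>= 1).
#' @param nPersons sample size (>= 1).
#' @return List with \code{neg2LL}, \code{AIC}, \code{BIC}.
#' @export
fitIndices <- function(neg2LL, nParams, nPersons) {
  if (nParams < 1) stop("nParams must be >= 1")
  if (nPersons < 1) stop("nPersons must be >= 1")
  list(neg2LL = neg2LL,
       AIC = neg2LL + 2 * nParams,
       BIC = neg2LL + nParams * log(nPersons))
}
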