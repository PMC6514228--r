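## EAP scoring: posterior mean and posterior-SD standard error on a
## quadrature grid, computed in log space.

## internal fast path: idx = bank row indices, sc = scores 1..5,
## lpArr = .logProbArray(bank, grid). Accumulates the log-likelihood over
## nodes in canonical (bank) order so the estimate is bit-for-bit invariant
## to administration order.
.eapCore <- function(idx, sc, lpArr, grid) {
  Q <- length(grid@nodes)
  ll <- numeric(Q)
  if (length(idx) > 0) {
    o <- order(idx)
    for (j in o) ll <- ll + lpArr[idx[j], sc[j], ]
  }
  lp <- ll + log(grid@weights)
  m <- max(lp)
  p <- exp(lp - m)
  p <- p / sum(p)
  theta <- sum(grid@nodes * p)
  se <- sqrt(sum((grid@nodes - theta)^2 * p))
  list(theta = theta, se = se)
}

#' Expected a posteriori (EAP) trait estimate
#'
#' Posterior mean of theta over a standard-normal prior discretized on a
#' quadrature grid; the standard error is the posterior standard deviation
#' on the same grid. With an empty pattern the prior mean and SD are
#' returned. Likelihoods are accumulated in log space, so long patterns do
#' not underflow, and terms are summed in bank order, making the estimate
#' bit-for-bit invariant to the order in which items were administered.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param itemIds character, administered item ids (possibly empty).
#' @param scores integer scores 1..5, same length as \code{itemIds}.
#' @param grid a \linkS4class{QuadratureGrid}
#'   (default \code{quadratureGrid()}).
#' @return A \linkS4class{ThetaEstimate}.
#' @examples
#' bank <- catIABank()
#' eapEstimate(bank, character(0), integer(0))           # prior: ~0, ~1
#' eapEstimate(bank, c("CIAT-81", "IAT-3"), c(4L, 3L))
#' @export
eapEstimate <- function(bank, itemIds, scores, grid = quadratureGrid()) {
  stopifnot(is(bank, "ItemBank"), is(grid, "QuadratureGrid"),
            length(itemIds) == length(scores))
  validObject(grid)
  if (length(scores) > 0 && any(scores < 1 | scores > 5))
    stop("scores must be in 1..5")
  idx <- .itemIndex(bank, itemIds)
  lpArr <- .logProbArray(bank, grid)
  r <- .eapCore(idx, as.integer(scores), lpArr, grid)
  new("ThetaEstimate", theta = r$theta, se = r$se,
      nItemsUsed = length(idx), trace = as.character(itemIds))
}

#' Score every person of a response matrix by EAP
#'
#' Non-adaptive (full-pattern) scoring of all persons on the items shared
#' between the response matrix and the bank.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param responses a \linkS4class{ResponseMatrix} whose item ids are all
#'   present in the bank.
#' @param grid a \linkS4class{QuadratureGrid}.
#' @return data.frame with one row per person: \code{person_id},
#'   \code{theta}, \code{se}.
#' @export
eapScore <- function(bank, responses, grid = quadratureGrid()) {
  stopifnot(is(bank, "ItemBank"), is(responses, "ResponseMatrix"))
  ids <- itemIds(responses)
  idx <- .itemIndex(bank, ids)
  X <- scoreMatrix(responses)
  lpArr <- .logProbArray(bank, grid)
  Q <- length(grid@nodes)
  n <- nrow(X)
  ll <- matrix(0, n, Q)
  o <- order(idx)
  for (j in o) ll <- ll + lpArr[idx[j], , ][X[, j], , drop = FALSE]
  lp <- sweep(ll, 2L, log(grid@weights), `+`)
  m <- apply(lp, 1L, max)
  p <- exp(lp - m)
  p <- p / rowSums(p)
  theta <- as.numeric(p %*% grid@nodes)
  ex2 <- as.numeric(p %*% (grid@nodes^2))
  se <- sqrt(pmax(ex2 - theta^2, 0))
  data.frame(person_id = rownames(X), theta = theta, se = se,
             stringsAsFactors = FALSE)
}

#' Simulate GRM responses for known trait values
#'
#' Draws one five-category response per person and item from the GRM
#' category probabilities at the person's true theta, via inverse-CDF
#' sampling on the boundary probabilities. Reproducible under a fixed seed.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param thetas numeric vector of true trait values (one per person).
#' @param seed integer seed, or \code{NA} to use the current RNG state.
#' @param personData optional covariate data.frame passed through to the
#'   result (a \code{true_theta} column is always added).
#' @return A \linkS4class{ResponseMatrix}.
#' @export
simulateResponses <- function(bank, thetas, seed = NA_integer_,
                              personData = NULL) {
  stopifnot(is(bank, "ItemBank"), all(is.finite(thetas)))
  if (!is.na(seed)) set.seed(as.integer(seed))
  par <- .bankPar(bank)
  n <- length(thetas); J <- length(par$a)
  X <- matrix(1L, n, J, dimnames = list(paste0("P", seq_len(n)), par$ids))
  U <- matrix(runif(n * J), n, J)
  for (k in 1:4) {
    ## P(X >= k+1 | theta) = plogis(a_j (theta - b_jk)); outer over persons
    pk <- plogis(outer(thetas, par$a) -
                 matrix(par$a * par$b[, k], n, J, byrow = TRUE))
    X <- X + (U < pk)
  }
  if (is.null(personData))
    personData <- data.frame(row.names = rownames(X))
  personData$true_theta <- thetas
  ResponseMatrix(X, personData = personData)
}
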