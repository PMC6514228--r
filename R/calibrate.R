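## Marginal maximum likelihood calibration of the GRM by EM.
##
## E-step: posterior weights of each person over the quadrature nodes under
## the current parameters and the N(0,1) prior. M-step: per item, maximize
## the expected complete-data log-likelihood sum_{q,c} r_{qc} log P_c(x_q)
## by quasi-Newton, with thresholds parameterized as (b1, log increments)
## so the ordering constraint b1 < b2 < b3 < b4 holds by construction.

## par vector <-> GRM parameters: (log a, b1, log d2, log d3, log d4)
.parToAB <- function(p) {
  a <- exp(p[1L])
  b <- p[2L] + c(0, cumsum(exp(p[3:5])))
  list(a = a, b = b)
}

.abToPar <- function(a, b) {
  c(log(a), b[1L], log(pmax(diff(b), 1e-3)))
}

## expected complete-data negative log-likelihood for one item
## r: Q x 5 expected counts; nodes: Q
.itemENLL <- function(p, r, nodes) {
  ab <- .parToAB(p)
  ps <- plogis(ab$a * outer(nodes, ab$b, `-`))     # Q x 4
  P <- cbind(1 - ps[, 1L], ps[, 1L] - ps[, 2L], ps[, 2L] - ps[, 3L],
             ps[, 3L] - ps[, 4L], ps[, 4L], deparse.level = 0)
  -sum(r * log(pmax(P, 1e-300)))
}

## analytic gradient of .itemENLL in the (log a, b1, log d2..d4) chart
.itemENLLGrad <- function(p, r, nodes) {
  ab <- .parToAB(p)
  a <- ab$a; b <- ab$b
  ps <- plogis(a * outer(nodes, b, `-`))           # Q x 4, s_k
  P <- cbind(1 - ps[, 1L], ps[, 1L] - ps[, 2L], ps[, 2L] - ps[, 3L],
             ps[, 3L] - ps[, 4L], ps[, 4L], deparse.level = 0)
  P <- pmax(P, 1e-300)
  W <- r / P                                        # Q x 5
  Qk <- ps * (1 - ps)                               # Q x 4
  D <- W[, 2:5, drop = FALSE] - W[, 1:4, drop = FALSE]  # r_{k+1}/P_{k+1}-r_k/P_k
  dfdb <- a * colSums(Qk * D)                       # length 4
  xb <- outer(nodes, b, `-`)
  dfda <- -sum(xb * Qk * D)
  d <- exp(p[3:5])
  c(a * dfda,
    sum(dfdb),
    d[1] * sum(dfdb[2:4]),
    d[2] * sum(dfdb[3:4]),
    d[3] * dfdb[4])
}

#' Calibrate GRM item parameters by marginal maximum likelihood (EM)
#'
#' Estimates one discrimination and four ordered thresholds per item from a
#' persons x items matrix of 1..5 scores, with a standard-normal latent
#' trait integrated out on a quadrature grid. Convergence is declared when
#' the change in -2 log-likelihood falls below \code{tol}; non-convergence
#' within \code{maxCycles} is flagged in the result, not silently ignored.
#'
#' Every item must show all five response categories: an unobserved category
#' leaves its threshold unidentified, so such items are rejected with an
#' error naming the item and the missing category.
#'
#' @param responses a \linkS4class{ResponseMatrix} (>= 2 items).
#' @param grid a \linkS4class{QuadratureGrid}.
#' @param tol absolute change in -2LL declaring convergence.
#' @param maxCycles maximum EM cycles.
#' @return A list with \code{bank} (the calibrated \linkS4class{ItemBank};
#'   source scale/domain metadata is carried over from the input when
#'   available), \code{neg2LL} (final marginal -2 log-likelihood),
#'   \code{nParams}, \code{iterations} and \code{converged}.
#' @export
calibrateGRM <- function(responses, grid = quadratureGrid(),
                         tol = 1e-4, maxCycles = 500L) {
  stopifnot(is(responses, "ResponseMatrix"), is(grid, "QuadratureGrid"))
  X <- scoreMatrix(responses)
  n <- nrow(X); J <- ncol(X)
  if (J < 2) stop("calibration requires at least 2 items")
  for (j in seq_len(J)) {
    seen <- sort(unique(X[, j]))
    if (length(seen) < 2)
      stop("item ", colnames(X)[j], " is single-category (only score ",
           seen, " observed)")
    missing <- setdiff(1:5, seen)
    if (length(missing) > 0)
      stop("item ", colnames(X)[j], " has unobserved categor",
           if (length(missing) > 1) "ies " else "y ",
           paste(missing, collapse = ", "),
           "; collapse categories or drop the item before calibration")
  }
  nodes <- grid@nodes; Q <- length(nodes); logw <- log(grid@weights)

  ## starting values: a = 1, thresholds from pooled cumulative proportions
  pars <- matrix(NA_real_, J, 5L)
  for (j in seq_len(J)) {
    pk <- vapply(1:4, function(k) mean(X[, j] >= k + 1), numeric(1))
    pk <- pmin(pmax(pk, 1e-3), 1 - 1e-3)
    b0 <- -qlogis(pk)
    b0 <- cummax(b0 + 1e-6 * (1:4))  # enforce strict ordering
    b0 <- b0 + (0:3) * 1e-3
    pars[j, ] <- .abToPar(1, b0)
  }

  itemLogLik <- function(pars) {
    ## n x Q log-likelihood matrix under current parameters
    ll <- matrix(0, n, Q)
    for (j in seq_len(J)) {
      ab <- .parToAB(pars[j, ])
      ps <- plogis(ab$a * outer(nodes, ab$b, `-`))
      P <- cbind(1 - ps[, 1L], ps[, 1L] - ps[, 2L], ps[, 2L] - ps[, 3L],
                 ps[, 3L] - ps[, 4L], ps[, 4L], deparse.level = 0)
      lP <- t(log(pmax(P, 1e-300)))           # 5 x Q
      ll <- ll + lP[X[, j], , drop = FALSE]
    }
    ll
  }

  deviance <- function(ll) {
    lp <- sweep(ll, 2L, logw, `+`)
    m <- apply(lp, 1L, max)
    -2 * sum(m + log(rowSums(exp(lp - m))))
  }

  ll <- itemLogLik(pars)
  dev <- deviance(ll)
  converged <- FALSE
  iter <- 0L
  while (iter < maxCycles) {
    iter <- iter + 1L
    ## E-step: posterior over nodes
    lp <- sweep(ll, 2L, logw, `+`)
    m <- apply(lp, 1L, max)
    post <- exp(lp - m)
    post <- post / rowSums(post)              # n x Q
    ## M-step: per-item expected counts and quasi-Newton update
    for (j in seq_len(J)) {
      r <- rowsum(post, group = factor(X[, j], levels = 1:5))  # 5 x Q
      r[is.na(r)] <- 0
      rq <- t(r)                                               # Q x 5
      opt <- optim(pars[j, ], .itemENLL, .itemENLLGrad, r = rq,
                   nodes = nodes, method = "BFGS",
                   control = list(maxit = 25, reltol = 1e-10))
      pars[j, ] <- opt$par
    }
    ll <- itemLogLik(pars)
    devNew <- deviance(ll)
    if (abs(dev - devNew) < tol) {
      dev <- devNew
      converged <- TRUE
      break
    }
    dev <- devNew
  }
  if (!converged)
    warning("EM did not converge within ", maxCycles,
            " cycles (last -2LL change above ", tol, ")")

  ab <- lapply(seq_len(J), function(j) .parToAB(pars[j, ]))
  meta <- as.data.frame(SummarizedExperiment::rowData(responses))
  items <- data.frame(
    item_id = colnames(X),
    source_scale = if ("source_scale" %in% names(meta))
      meta$source_scale else rep("IAT", J),
    domain = if ("domain" %in% names(meta))
      meta$domain else rep("salience", J),
    label = if ("label" %in% names(meta)) meta$label else colnames(X),
    a = vapply(ab, `[[`, numeric(1), "a"),
    b1 = vapply(ab, function(x) x$b[1], numeric(1)),
    b2 = vapply(ab, function(x) x$b[2], numeric(1)),
    b3 = vapply(ab, function(x) x$b[3], numeric(1)),
    b4 = vapply(ab, function(x) x$b[4], numeric(1)),
    stringsAsFactors = FALSE)
  list(bank = ItemBank(items), neg2LL = dev, nParams = 5L * J,
       iterations = iter, converged = converged)
}
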