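## Item-bank quality-control statistics: unidimensionality screen (eigen
## decomposition of the inter-item Pearson correlation matrix), Yen's Q3
## residual correlations, Mokken scalability coefficients, S-X2 item fit
## with the Lord-Wingersky summed-score recursion, and ordinal-logistic DIF
## with McFadden pseudo-R2 change.

#' QC decision thresholds
#'
#' Default cut-offs for the six-step item-bank construction pipeline: the
#' first factor must explain at least 20% of the variance and dominate the
#' second factor by a ratio of at least 4; items need a first-factor loading
#' of at least 0.40; pairwise Q3 above 0.36 flags local dependence; item
#' scalability below 0.30 flags non-monotonicity; S-X2 p below 0.01 flags
#' misfit; a McFadden R-squared change above 0.02 flags DIF; discrimination
#' below 1.00 flags a weak item.
#'
#' @param efaFirstFactorMin minimum first-factor variance proportion.
#' @param efaRatioMin minimum first/second eigenvalue ratio.
#' @param loadingMin minimum first-factor loading.
#' @param q3Max maximum pairwise residual correlation.
#' @param hMin minimum item scalability coefficient.
#' @param sx2Alpha item-fit significance level.
#' @param difR2ChangeMax maximum McFadden R-squared change.
#' @param aMin minimum discrimination.
#' @return A named list of thresholds.
#' @export
qcThresholds <- function(efaFirstFactorMin = 0.20, efaRatioMin = 4,
                         loadingMin = 0.40, q3Max = 0.36, hMin = 0.30,
                         sx2Alpha = 0.01, difR2ChangeMax = 0.02,
                         aMin = 1.00) {
  stopifnot(efaFirstFactorMin > 0, efaFirstFactorMin < 1, efaRatioMin > 0,
            loadingMin > 0, loadingMin < 1, q3Max > 0, q3Max < 1,
            sx2Alpha > 0, sx2Alpha < 1, difR2ChangeMax > 0, aMin >= 0)
  list(efaFirstFactorMin = efaFirstFactorMin, efaRatioMin = efaRatioMin,
       loadingMin = loadingMin, q3Max = q3Max, hMin = hMin,
       sx2Alpha = sx2Alpha, difR2ChangeMax = difR2ChangeMax, aMin = aMin)
}

#' Unidimensionality screen by eigen decomposition
#'
#' Eigen decomposition of the inter-item Pearson correlation matrix of the
#' 1..5 scores. The screen reports the first-factor variance proportion
#' (lambda1 / p), the first/second eigenvalue ratio, and the first-factor
#' loadings (first eigenvector scaled by sqrt(lambda1), sign-aligned so most
#' loadings are positive); items loading below \code{loadingMin} are listed
#' for exclusion.
#'
#' @param responses a \linkS4class{ResponseMatrix} (>= 3 items, >= 2
#'   persons, no constant items).
#' @param thresholds a \code{\link{qcThresholds}} list.
#' @return List with \code{proportion}, \code{ratio}, \code{loadings}
#'   (named), \code{excluded} (item ids), \code{pass} (logical: pool-level
#'   screen).
#' @export
efaScreen <- function(responses, thresholds = qcThresholds()) {
  stopifnot(is(responses, "ResponseMatrix"))
  X <- scoreMatrix(responses)
  if (ncol(X) < 3) stop("need at least 3 items")
  if (nrow(X) < 2) stop("need at least 2 persons")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0))
    stop("constant item(s), correlation undefined: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  R <- cor(X)
  e <- eigen(R, symmetric = TRUE)
  lambda <- e$values
  loadings <- e$vectors[, 1L] * sqrt(lambda[1L])
  if (sum(loadings) < 0) loadings <- -loadings
  names(loadings) <- colnames(X)
  proportion <- lambda[1L] / ncol(X)
  ratio <- lambda[1L] / lambda[2L]
  excluded <- names(loadings)[loadings < thresholds$loadingMin]
  list(proportion = proportion, ratio = ratio, loadings = loadings,
       excluded = excluded,
       pass = proportion >= thresholds$efaFirstFactorMin &&
              ratio >= thresholds$efaRatioMin)
}

#' Yen's Q3 local-dependence statistic
#'
#' For each person, residuals d_j = x_j - E[x_j | thetaHat] are formed from
#' the GRM expected score at the person's EAP estimate; Q3(j, k) is the
#' Pearson correlation of the residual columns. Pairs above \code{q3Max}
#' are flagged. A zero-variance residual column makes the pair undefined
#' (NA), which is reported rather than silently zeroed.
#'
#' @param responses a \linkS4class{ResponseMatrix}.
#' @param bank calibrated \linkS4class{ItemBank} covering all items.
#' @param grid a \linkS4class{QuadratureGrid}.
#' @param thresholds a \code{\link{qcThresholds}} list.
#' @return List with \code{q3} (symmetric matrix, NA diagonal),
#'   \code{flagged} (data.frame item_i, item_j, q3, sorted by decreasing
#'   Q3), \code{undefined} (data.frame of undefined pairs, if any).
#' @export
q3Matrix <- function(responses, bank, grid = quadratureGrid(),
                     thresholds = qcThresholds()) {
  stopifnot(is(responses, "ResponseMatrix"), is(bank, "ItemBank"))
  X <- scoreMatrix(responses)
  idx <- .itemIndex(bank, colnames(X))
  theta <- eapScore(bank, responses, grid)$theta
  par <- .bankPar(bank)
  ## expected score 1..5 at each person's thetaHat, per item
  E <- vapply(seq_along(idx), function(jj) {
    j <- idx[jj]
    ps <- plogis(outer(theta, rep(par$a[j], 4)) -
                 matrix(par$a[j] * par$b[j, ], length(theta), 4,
                        byrow = TRUE))
    1 + rowSums(ps)
  }, numeric(nrow(X)))
  D <- X - E
  sds <- apply(D, 2L, sd)
  q3 <- suppressWarnings(cor(D))
  diag(q3) <- NA_real_
  dimnames(q3) <- list(colnames(X), colnames(X))
  ut <- which(upper.tri(q3), arr.ind = TRUE)
  vals <- q3[ut]
  flagged <- data.frame(item_i = colnames(X)[ut[, 1L]],
                        item_j = colnames(X)[ut[, 2L]], q3 = vals,
                        stringsAsFactors = FALSE)
  undefined <- flagged[is.na(flagged$q3), c("item_i", "item_j")]
  flagged <- flagged[!is.na(flagged$q3) & flagged$q3 > thresholds$q3Max, ]
  flagged <- flagged[order(-flagged$q3), ]
  rownames(flagged) <- NULL
  list(q3 = q3, flagged = flagged, undefined = undefined,
       zeroVarianceItems = colnames(X)[sds == 0])
}

## internal: maximum covariance between two ordinal items given their
## margins (comonotonic coupling), population (divide-by-n) convention
.covMax <- function(tx, ty) {
  n <- sum(tx)
  Fx <- cumsum(tx) / n; Fy <- cumsum(ty) / n
  u <- sort(unique(c(Fx, Fy)))
  u <- u[u > 1e-12]
  lo <- c(0, head(u, -1))
  ## category covering quantile segment (lo, u]: smallest c with F(c) >= u
  xc <- vapply(u, function(p) which(Fx >= p - 1e-12)[1L], integer(1))
  yc <- vapply(u, function(p) which(Fy >= p - 1e-12)[1L], integer(1))
  exy <- sum((u - lo) * as.numeric(names(tx))[xc] *
               as.numeric(names(ty))[yc])
  ex <- sum(as.numeric(names(tx)) * tx) / n
  ey <- sum(as.numeric(names(ty)) * ty) / n
  exy - ex * ey
}

#' Mokken scalability coefficients
#'
#' Pairwise coefficients H_jk = cov(X_j, X_k) / covmax(X_j, X_k), where the
#' maximum covariance given the observed margins is attained by the
#' comonotonic (Guttman-ordered) joint distribution; item coefficients H_j
#' and the scale coefficient H are the corresponding ratios of summed
#' covariances. Items with H_j below \code{hMin} are listed for exclusion.
#'
#' @param responses a \linkS4class{ResponseMatrix} (>= 2 items, no
#'   zero-variance items).
#' @param thresholds a \code{\link{qcThresholds}} list.
#' @return List with \code{H} (scale), \code{Hj} (named item
#'   coefficients), \code{Hjk} (pairwise matrix), \code{excluded}.
#' @export
mokkenScalability <- function(responses, thresholds = qcThresholds()) {
  stopifnot(is(responses, "ResponseMatrix"))
  X <- scoreMatrix(responses)
  J <- ncol(X)
  if (J < 2) stop("need at least 2 items")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance item(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  n <- nrow(X)
  margins <- lapply(seq_len(J), function(j)
    table(factor(X[, j], levels = 1:5)))
  S <- cov(X) * (n - 1) / n   # population covariance
  Smax <- matrix(NA_real_, J, J, dimnames = dimnames(S))
  for (j in seq_len(J - 1)) for (k in (j + 1):J) {
    m <- .covMax(margins[[j]], margins[[k]])
    Smax[j, k] <- Smax[k, j] <- m
  }
  Hjk <- S / Smax
  diag(Hjk) <- NA_real_
  Hj <- vapply(seq_len(J), function(j)
    sum(S[j, -j]) / sum(Smax[j, -j]), numeric(1))
  names(Hj) <- colnames(X)
  H <- sum(S[upper.tri(S)]) / sum(Smax[upper.tri(Smax)])
  list(H = H, Hj = Hj, Hjk = Hjk,
       excluded = names(Hj)[Hj < thresholds$hMin])
}

#' Lord-Wingersky summed-score recursion
#'
#' Distribution of the summed score (internal coding 0..4 per item) over a
#' set of GRM items at each quadrature node, built by convolving item
#' category probabilities one item at a time.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param grid a \linkS4class{QuadratureGrid}.
#' @param items optional subset of item ids/positions.
#' @return Matrix of dimension (4 * nItems + 1) x nNodes; row s+1 holds
#'   P(summed score = s | theta = node).
#' @export
lordWingersky <- function(bank, grid = quadratureGrid(), items = NULL) {
  stopifnot(is(bank, "ItemBank"))
  if (!is.null(items)) bank <- bank[.itemIndex(bank, items)]
  par <- .bankPar(bank)
  J <- length(par$a); Q <- length(grid@nodes)
  if (J == 0) stop("empty item subset")
  dist <- matrix(0, 1L, Q)
  dist[1L, ] <- 1
  for (j in seq_len(J)) {
    P <- t(vapply(grid@nodes, function(th)
      .catProbs(par$a[j], par$b[j, , drop = FALSE], th)[1L, ],
      numeric(5)))                      # Q x 5
    S <- nrow(dist)
    new <- matrix(0, S + 4L, Q)
    for (c in 0:4)
      new[(1:S) + c, ] <- new[(1:S) + c, ] + dist * rep(P[, c + 1L],
                                                        each = S)
    dist <- new
  }
  rownames(dist) <- 0:(4 * J)
  dist
}

#' S-X2 item fit
#'
#' Orlando-Thissen style fit statistic: within groups defined by the summed
#' rest score (all other items), observed category frequencies are compared
#' with model-expected frequencies obtained from the Lord-Wingersky
#' recursion over the remaining items and the quadrature prior. Cells with
#' expected count below \code{minExpected} are collapsed toward adjacent
#' cells (rest-score groups are merged inward from both extremes first, then
#' adjacent categories within a group). The statistic is
#' X2 = sum (O - E)^2 / E with df = (cells after collapsing - number of
#' groups) - 5 free item parameters; items whose df fall to zero or below
#' are reported untestable (NA p).
#'
#' @param responses a \linkS4class{ResponseMatrix}.
#' @param bank calibrated \linkS4class{ItemBank} covering the items.
#' @param grid a \linkS4class{QuadratureGrid}.
#' @param minExpected minimum expected cell count before collapsing.
#' @param thresholds a \code{\link{qcThresholds}} list.
#' @return data.frame with one row per item: \code{item_id}, \code{sx2},
#'   \code{df}, \code{p}, \code{flagged} (p below \code{sx2Alpha}),
#'   \code{untestable}.
#' @export
sx2ItemFit <- function(responses, bank, grid = quadratureGrid(),
                       minExpected = 1, thresholds = qcThresholds()) {
  stopifnot(is(responses, "ResponseMatrix"), is(bank, "ItemBank"))
  X <- scoreMatrix(responses)
  ids <- colnames(X)
  idx <- .itemIndex(bank, ids)
  J <- ncol(X); n <- nrow(X)
  w <- grid@weights
  out <- data.frame(item_id = ids, sx2 = NA_real_, df = NA_integer_,
                    p = NA_real_, flagged = FALSE, untestable = FALSE,
                    stringsAsFactors = FALSE)
  Xint <- X - 1L
  for (jj in seq_len(J)) {
    restBank <- bank[idx[-jj]]
    fRest <- lordWingersky(restBank, grid)       # (S+1) x Q
    Smax <- nrow(fRest) - 1L
    itemP <- t(vapply(grid@nodes, function(th)
      .catProbs(bank@items$a[idx[jj]],
                as.matrix(bank@items[idx[jj], c("b1", "b2", "b3", "b4")]),
                th)[1L, ], numeric(5)))          # Q x 5
    ## expected P(category c | rest score s) over prior
    denom <- as.numeric(fRest %*% w)             # P(rest = s)
    Ep <- matrix(0, Smax + 1L, 5L)
    for (c in 1:5)
      Ep[, c] <- as.numeric(fRest %*% (w * itemP[, c]))
    ok <- denom > 0
    Ep[ok, ] <- Ep[ok, ] / denom[ok]
    ## observed
    rest <- rowSums(Xint) - Xint[, jj]
    O <- matrix(0, Smax + 1L, 5L)
    tab <- table(factor(rest, levels = 0:Smax),
                 factor(X[, jj], levels = 1:5))
    O[] <- as.numeric(tab)
    Ns <- rowSums(O)
    keep <- Ns > 0
    O <- O[keep, , drop = FALSE]
    E <- Ep[keep, , drop = FALSE] * Ns[keep]
    ## collapse rest-score rows inward from both extremes until each row
    ## has total expected mass >= 5 * minExpected
    rowOK <- function(E) rowSums(E) >= 5 * minExpected
    while (nrow(E) > 1 && !rowOK(E)[1L]) {
      E[2L, ] <- E[2L, ] + E[1L, ]; O[2L, ] <- O[2L, ] + O[1L, ]
      E <- E[-1L, , drop = FALSE]; O <- O[-1L, , drop = FALSE]
    }
    while (nrow(E) > 1 && !rowOK(E)[nrow(E)]) {
      m <- nrow(E)
      E[m - 1L, ] <- E[m - 1L, ] + E[m, ]; O[m - 1L, ] <- O[m - 1L, ] + O[m, ]
      E <- E[-m, , drop = FALSE]; O <- O[-m, , drop = FALSE]
    }
    ## within each row, collapse adjacent category cells from the extremes
    ## inward while any expected cell is below minExpected
    sx2 <- 0; cells <- 0L; groups <- nrow(E)
    for (r in seq_len(nrow(E))) {
      e <- E[r, ]; o <- O[r, ]
      while (length(e) > 1 && e[1L] < minExpected) {
        e[2L] <- e[2L] + e[1L]; o[2L] <- o[2L] + o[1L]
        e <- e[-1L]; o <- o[-1L]
      }
      while (length(e) > 1 && e[length(e)] < minExpected) {
        L <- length(e)
        e[L - 1L] <- e[L - 1L] + e[L]; o[L - 1L] <- o[L - 1L] + o[L]
        e <- e[-L]; o <- o[-L]
      }
      while (length(e) > 1 && any(e < minExpected)) {
        i <- which(e < minExpected)[1L]
        nb <- if (i == length(e)) i - 1L else i + 1L
        e[nb] <- e[nb] + e[i]; o[nb] <- o[nb] + o[i]
        e <- e[-i]; o <- o[-i]
      }
      sx2 <- sx2 + sum((o - e)^2 / e)
      cells <- cells + length(e)
    }
    df <- (cells - groups) - 5L
    out$sx2[jj] <- sx2
    out$df[jj] <- df
    if (df <= 0) {
      out$untestable[jj] <- TRUE
    } else {
      out$p[jj] <- pchisq(sx2, df, lower.tail = FALSE)
      out$flagged[jj] <- out$p[jj] < thresholds$sx2Alpha
    }
  }
  out
}

#' DIF screen by ordinal logistic regression
#'
#' For each item, nested proportional-odds (cumulative logit) models are
#' fitted on the matching trait estimate: M1 (trait only) and M3 (trait +
#' group + trait-by-group interaction). McFadden's pseudo-R2 is
#' 1 - logLik(model)/logLik(null) with an intercepts-only null; an item is
#' flagged when the R-squared change R2(M3) - R2(M1) exceeds
#' \code{difR2ChangeMax} (uniform plus non-uniform DIF combined). The
#' intermediate M2 (trait + group) comparisons are returned as well.
#'
#' @param responses a \linkS4class{ResponseMatrix}.
#' @param group name of a two-level person covariate in
#'   \code{personData(responses)}, or a vector of two-level labels.
#' @param bank calibrated \linkS4class{ItemBank} (matching variable is the
#'   EAP estimate on this bank).
#' @param grid a \linkS4class{QuadratureGrid}.
#' @param thresholds a \code{\link{qcThresholds}} list.
#' @param theta optional precomputed matching variable (overrides the EAP
#'   scoring step).
#' @return data.frame per item: \code{item_id}, \code{r2_m1},
#'   \code{r2_m2}, \code{r2_m3}, \code{deltaR2} (M3 - M1),
#'   \code{deltaR2_uniform} (M2 - M1), \code{flagged}, \code{untestable}.
#' @export
difOrdinalLogistic <- function(responses, group, bank,
                               grid = quadratureGrid(),
                               thresholds = qcThresholds(),
                               theta = NULL) {
  stopifnot(is(responses, "ResponseMatrix"), is(bank, "ItemBank"))
  X <- scoreMatrix(responses)
  if (is.character(group) && length(group) == 1L) {
    pd <- personData(responses)
    if (!(group %in% names(pd)))
      stop("grouping variable not found in personData: ", group)
    g <- pd[[group]]
  } else g <- group
  if (anyNA(g)) stop("grouping variable contains missing codes")
  g <- factor(g)
  if (nlevels(g) != 2L)
    stop("grouping variable must have exactly two levels, got ",
         nlevels(g))
  if (is.null(theta)) theta <- eapScore(bank, responses, grid)$theta
  stopifnot(length(theta) == nrow(X))
  gNum <- as.numeric(g == levels(g)[2L])
  out <- data.frame(item_id = colnames(X), r2_m1 = NA_real_,
                    r2_m2 = NA_real_, r2_m3 = NA_real_,
                    deltaR2 = NA_real_, deltaR2_uniform = NA_real_,
                    flagged = FALSE, untestable = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X))) {
    y <- factor(X[, j], ordered = TRUE)
    if (nlevels(y) < 2L) {
      out$untestable[j] <- TRUE
      next
    }
    ## null log-likelihood: intercepts only (observed category proportions)
    tab <- table(y)
    ll0 <- sum(tab * log(tab / sum(tab)))
    fit <- function(formula, data) {
      f <- tryCatch(
        suppressWarnings(MASS::polr(formula, data = data, Hess = FALSE)),
        error = function(e) NULL)
      if (is.null(f)) return(NA_real_)
      as.numeric(logLik(f))
    }
    d <- data.frame(y = y, th = theta, g = gNum)
    ll1 <- fit(y ~ th, d)
    ll2 <- fit(y ~ th + g, d)
    ll3 <- fit(y ~ th + g + th:g, d)
    if (anyNA(c(ll1, ll2, ll3))) {
      out$untestable[j] <- TRUE
      next
    }
    out$r2_m1[j] <- 1 - ll1 / ll0
    out$r2_m2[j] <- 1 - ll2 / ll0
    out$r2_m3[j] <- 1 - ll3 / ll0
    out$deltaR2[j] <- out$r2_m3[j] - out$r2_m1[j]
    out$deltaR2_uniform[j] <- out$r2_m2[j] - out$r2_m1[j]
    out$flagged[j] <- out$deltaR2[j] > thresholds$difR2ChangeMax
  }
  out
}

#' Discrimination filter
#'
#' Lists items whose discrimination falls below \code{aMin} (default 1.00).
#'
#' @param bank a calibrated \linkS4class{ItemBank}.
#' @param thresholds a \code{\link{qcThresholds}} list.
#' @return Character vector of excluded item ids (possibly empty).
#' @export
discriminationFilter <- function(bank, thresholds = qcThresholds()) {
  stopifnot(is(bank, "ItemBank"))
  a <- discrimination(bank)
  names(a)[a < thresholds$aMin]
}
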