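## Synthetic-data generators: N(0,1) trait populations with covariates and
## diagnosis labels, GRM item banks with realistic parameter ranges, and
## response matrices with optional planted QC defects (pure-noise item, low
## discrimination, DIF shift, locally dependent pair, secondary dimension).

#' Describe a synthetic study design
#'
#' Defaults emulate the calibration study the packaged bank came from: a
#' standard-normal trait, five-category GRM items with discriminations
#' drawn uniformly on [1.1, 2.6] and ordered thresholds spanning about
#' [-2, 3.5], covariate rates close to the reference sample (female 50.2%,
#' rural 58.9%, under-18 34%), and a diagnosis defined as theta above 1.0
#' with 5% label noise.
#'
#' Planted defects (a list of lists, each with a \code{type} field):
#' \itemize{
#'   \item \code{list(type = "noise_item", item = i)} - item i responds
#'     uniformly on 1..5, independent of theta.
#'   \item \code{list(type = "low_a_item", item = i, a = 0.9)} - item i is
#'     generated (and calibrates to) a weak discrimination.
#'   \item \code{list(type = "dif_item", item = i, group = "gender",
#'     shift = 0.8)} - item i's thresholds are shifted upward by
#'     \code{shift} for the second level of the grouping covariate.
#'   \item \code{list(type = "dependent_pair", item = i, partner = k,
#'     noise = 0.1)} - item i copies item k's response, re-drawn from the
#'     item's own GRM with probability \code{noise}.
#'   \item \code{list(type = "second_factor", items = c(...),
#'     loading = 0.8)} - the listed items load on an extra independent
#'     latent variable with the given slope.
#' }
#'
#' @param nPersons number of persons.
#' @param nItems number of items.
#' @param aRange discrimination range (uniform draw).
#' @param thresholdRange span of the ordered thresholds.
#' @param defects list of planted defects (see Details).
#' @param covariates named list of Bernoulli rates for two-level covariates
#'   (probability of the second level).
#' @param diagnosisCut theta threshold defining a positive diagnosis.
#' @param diagnosisNoise probability of flipping a diagnosis label.
#' @param seed integer seed.
#' @return A design list consumed by the generators.
#' @export
syntheticDesign <- function(nPersons = 1000L, nItems = 20L,
                            aRange = c(1.1, 2.6),
                            thresholdRange = c(-2, 3.5),
                            defects = list(),
                            covariates = list(gender = 0.502,
                                              age_group = 0.34,
                                              region = 0.589),
                            diagnosisCut = 1.0, diagnosisNoise = 0.05,
                            seed = 1L) {
  stopifnot(nPersons >= 1, nItems >= 2, aRange[1] > 0,
            aRange[1] <= aRange[2],
            thresholdRange[1] < thresholdRange[2],
            diagnosisNoise >= 0, diagnosisNoise <= 1)
  for (d in defects) {
    stopifnot(!is.null(d$type))
    ii <- c(d$item, d$partner, d$items)
    if (!is.null(ii)) stopifnot(all(ii >= 1), all(ii <= nItems))
  }
  stopifnot(all(unlist(covariates) >= 0), all(unlist(covariates) <= 1))
  list(nPersons = as.integer(nPersons), nItems = as.integer(nItems),
       aRange = aRange, thresholdRange = thresholdRange,
       defects = defects, covariates = covariates,
       diagnosisCut = diagnosisCut, diagnosisNoise = diagnosisNoise,
       seed = as.integer(seed))
}

## defects of a given type
.defectsOf <- function(design, type) {
  Filter(function(d) identical(d$type, type), design$defects)
}

#' Generate a synthetic population
#'
#' True traits theta ~ N(0, 1); two-level covariates drawn Bernoulli at the
#' design's rates (levels coded as e.g. \code{female}/\code{male} for
#' gender, \code{groupA}/\code{groupB} otherwise); diagnosis labels are
#' \code{theta > diagnosisCut}, with labels flipped independently at the
#' \code{diagnosisNoise} rate.
#'
#' @param design a \code{\link{syntheticDesign}}.
#' @return data.frame with \code{true_theta}, one column per covariate, and
#'   logical \code{diagnosis}.
#' @export
generatePopulation <- function(design) {
  set.seed(design$seed)
  n <- design$nPersons
  theta <- rnorm(n)
  out <- data.frame(true_theta = theta)
  lv <- list(gender = c("female", "male"),
             age_group = c("18plus", "under18"),
             region = c("urban", "rural"))
  for (nm in names(design$covariates)) {
    levs <- if (nm %in% names(lv)) lv[[nm]] else
      paste0(nm, c("_A", "_B"))
    out[[nm]] <- levs[1L + rbinom(n, 1L, design$covariates[[nm]])]
  }
  lab <- theta > design$diagnosisCut
  flip <- runif(n) < design$diagnosisNoise
  out$diagnosis <- xor(lab, flip)
  rownames(out) <- paste0("P", seq_len(n))
  out
}

## marginal probability of the top category over a N(0,1) trait
.topCatMass <- function(a, b4) {
  x <- seq(-5, 5, length.out = 201)
  w <- dnorm(x); w <- w / sum(w)
  sum(w * plogis(a * (x - b4)))
}

#' Generate a synthetic GRM item bank
#'
#' Discriminations are uniform on the design's \code{aRange}; thresholds
#' start at b1 ~ U(-2, 0.2) with three positive increments, compressed
#' proportionally if b4 would exceed the top of \code{thresholdRange}, so
#' ordering always holds. For sharp items the upper thresholds are
#' additionally compressed until the top response category keeps at least
#' 1% marginal mass under a N(0, 1) trait; published banks show the same
#' pattern (their sharpest items carry the lowest top thresholds), and it
#' keeps all five categories observable at calibration sample sizes. A
#' \code{low_a_item} defect overrides the drawn discrimination for that
#' item. Source scales and domains are assigned round-robin so downstream
#' provenance summaries have realistic structure.
#'
#' @param design a \code{\link{syntheticDesign}}.
#' @return An \linkS4class{ItemBank}.
#' @export
generateBank <- function(design) {
  set.seed(design$seed + 1L)
  J <- design$nItems
  a <- runif(J, design$aRange[1], design$aRange[2])
  for (d in .defectsOf(design, "low_a_item"))
    a[d$item] <- if (is.null(d$a)) 0.9 else d$a
  lo <- design$thresholdRange[1]; hi <- design$thresholdRange[2]
  b <- matrix(NA_real_, J, 4)
  for (j in seq_len(J)) {
    b1 <- runif(1, lo, lo + 0.55 * (hi - lo) - 1.2)
    g <- runif(3, 0.4, 1.4)
    if (b1 + sum(g) > hi) g <- g * (hi - b1) / sum(g)
    bj <- b1 + c(0, cumsum(g))
    if (.topCatMass(a[j], bj[4]) < 0.01) {
      b4new <- uniroot(function(x) .topCatMass(a[j], x) - 0.01,
                       lower = bj[1] + 0.3, upper = bj[4])$root
      bj <- bj[1] + (bj - bj[1]) * (b4new - bj[1]) / (bj[4] - bj[1])
    }
    b[j, ] <- bj
  }
  items <- data.frame(
    item_id = sprintf("SYN-%02d", seq_len(J)),
    source_scale = rep(.SOURCE_SCALES, length.out = J),
    domain = rep(.DOMAINS, length.out = J),
    label = sprintf("synthetic item %d", seq_len(J)),
    a = a, b1 = b[, 1], b2 = b[, 2], b3 = b[, 3], b4 = b[, 4],
    stringsAsFactors = FALSE)
  ItemBank(items)
}

#' Generate synthetic responses with planted defects
#'
#' Clean items follow the GRM at each person's true theta. Planted defects
#' overwrite the clean draws: noise items respond uniformly; DIF items use
#' thresholds shifted by \code{shift} for the second level of the grouping
#' covariate; dependent-pair items copy their partner's response except for
#' a fresh model draw at the \code{noise} rate; second-factor items add an
#' independent latent variable times \code{loading} to the person's theta.
#'
#' @param bank an \linkS4class{ItemBank} from \code{\link{generateBank}}.
#' @param population data.frame from \code{\link{generatePopulation}}.
#' @param design the same \code{\link{syntheticDesign}}.
#' @return A \linkS4class{ResponseMatrix} carrying the population columns
#'   as person covariates and the bank's provenance as item metadata.
#' @export
generateResponses <- function(bank, population, design) {
  stopifnot(is(bank, "ItemBank"))
  set.seed(design$seed + 2L)
  theta <- population$true_theta
  n <- length(theta)
  par <- .bankPar(bank)
  J <- length(par$a)
  drawItem <- function(j, th, a = par$a[j], b = par$b[j, ]) {
    ps <- plogis(outer(th, rep(a, 4)) -
                 matrix(a * b, length(th), 4, byrow = TRUE))
    1L + rowSums(runif(length(th)) < ps)
  }
  X <- matrix(NA_integer_, n, J,
              dimnames = list(rownames(population), par$ids))
  ## second factor: affected items see theta + loading * z
  z <- rnorm(n)
  sfItems <- integer(0); sfLoad <- 0
  for (d in .defectsOf(design, "second_factor")) {
    sfItems <- d$items
    sfLoad <- if (is.null(d$loading)) 0.8 else d$loading
  }
  for (j in seq_len(J)) {
    th <- if (j %in% sfItems) theta + sfLoad * z else theta
    X[, j] <- drawItem(j, th)
  }
  for (d in .defectsOf(design, "noise_item"))
    X[, d$item] <- sample.int(5L, n, replace = TRUE)
  for (d in .defectsOf(design, "dif_item")) {
    gname <- if (is.null(d$group)) "gender" else d$group
    shift <- if (is.null(d$shift)) 0.8 else d$shift
    g <- factor(population[[gname]])
    aff <- g == levels(g)[2L]
    X[aff, d$item] <- drawItem(d$item, theta[aff],
                               b = par$b[d$item, ] + shift)
  }
  for (d in .defectsOf(design, "dependent_pair")) {
    noise <- if (is.null(d$noise)) 0.1 else d$noise
    redraw <- runif(n) < noise
    X[, d$item] <- ifelse(redraw, drawItem(d$item, theta), X[, d$partner])
  }
  rm <- ResponseMatrix(X, personData = population)
  SummarizedExperiment::rowData(rm) <- S4Vectors::DataFrame(
    bank@items[, c("source_scale", "domain", "label")],
    row.names = par$ids)
  rm
}
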