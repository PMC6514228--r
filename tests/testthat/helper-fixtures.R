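## Shared fixtures and independent oracles. Oracles deliberately avoid the
## package's own computational paths (direct formulas, enumeration).

## small deterministic bank built inline (no generator involved)
tinyBank <- function() {
  ItemBank(data.frame(
    item_id = c("T-1", "T-2", "T-3", "T-4"),
    source_scale = c("IAT", "GPIUS", "GAS", "CIAT"),
    domain = c("salience", "tolerance", "withdrawal", "benefits"),
    label = paste("tiny item", 1:4),
    a  = c(1.2, 2.0, 1.6, 0.9),
    b1 = c(-1.5, -0.8, -1.0, -2.0),
    b2 = c(-0.5, 0.1, 0.0, -0.8),
    b3 = c(0.6, 1.0, 1.1, 0.5),
    b4 = c(1.8, 2.2, 2.4, 1.9),
    stringsAsFactors = FALSE))
}

## direct logistic evaluation, independent of the package internals
oracleCatProbs <- function(a, b, theta) {
  ps <- 1 / (1 + exp(-a * (theta - b)))
  c(1 - ps[1], ps[1] - ps[2], ps[2] - ps[3], ps[3] - ps[4], ps[4])
}

## brute-force EAP on a dense grid, written from the posterior definition
oracleEAP <- function(bank, ids, scores, nGrid = 10001L) {
  x <- seq(-4, 4, length.out = nGrid)
  w <- exp(-x^2 / 2)
  w <- w / sum(w)
  it <- itemParameters(bank)
  ll <- rep(0, nGrid)
  for (j in seq_along(ids)) {
    row <- it[it$item_id == ids[j], ]
    ps <- 1 / (1 + exp(-row$a *
      outer(x, as.numeric(row[c("b1", "b2", "b3", "b4")]), `-`)))
    P <- cbind(1 - ps[, 1], ps[, 1] - ps[, 2], ps[, 2] - ps[, 3],
               ps[, 3] - ps[, 4], ps[, 4])
    ll <- ll + log(P[, scores[j]])
  }
  post <- exp(ll - max(ll)) * w
  post <- post / sum(post)
  m <- sum(x * post)
  list(theta = m, se = sqrt(sum((x - m)^2 * post)))
}

## pairwise-enumeration AUC with half-credit ties
oracleAUC <- function(pred, labels) {
  x <- pred[labels]; y <- pred[!labels]
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot / (length(x) * length(y))
}

## the planted-defect pool used for pipeline sensitivity checks
plantedDesign <- function(seed, nPersons = 1000L) {
  syntheticDesign(
    nPersons = nPersons, nItems = 20L, seed = seed,
    defects = list(
      list(type = "noise_item", item = 3L),
      list(type = "noise_item", item = 17L),
      list(type = "dependent_pair", item = 8L, partner = 9L, noise = 0.1),
      list(type = "dif_item", item = 12L, group = "gender", shift = 0.8),
      list(type = "low_a_item", item = 5L, a = 0.6)))
}

cleanDesign <- function(seed, nPersons = 1000L, nItems = 20L) {
  syntheticDesign(nPersons = nPersons, nItems = nItems, seed = seed)
}

makeResponses <- function(design) {
  pop <- generatePopulation(design)
  bank <- generateBank(design)
  list(bank = bank, pop = pop,
       responses = generateResponses(bank, pop, design))
}
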