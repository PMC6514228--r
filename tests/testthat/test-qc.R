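## one calibrated clean-data fixture shared across the QC tests
fxClean <- makeResponses(cleanDesign(600))
calClean <- calibrateGRM(fxClean$responses)

test_that("the eigenvalue screen certifies one-factor data and spots noise", {
  efa <- efaScreen(fxClean$responses)
  expect_gt(efa$proportion, 0.20)
  expect_gt(efa$ratio, 4)
  expect_length(efa$excluded, 0)
  expect_true(efa$pass)

  ## two independent 10-item factors: the dominance ratio collapses
  a <- makeResponses(cleanDesign(601, nItems = 10L))
  b <- makeResponses(cleanDesign(602, nItems = 10L))
  Xa <- scoreMatrix(a$responses); Xb <- scoreMatrix(b$responses)
  colnames(Xb) <- paste0("B-", 1:10)
  two <- ResponseMatrix(cbind(Xa, Xb))
  efa2 <- efaScreen(two)
  expect_lt(efa2$ratio, 2)
  expect_false(efa2$pass)

  ## a planted pure-noise item loads near zero and is flagged
  desN <- syntheticDesign(nPersons = 1000L, nItems = 20L, seed = 603,
                          defects = list(list(type = "noise_item",
                                              item = 7L)))
  fxN <- makeResponses(desN)
  efaN <- efaScreen(fxN$responses)
  expect_lt(efaN$loadings["SYN-07"], 0.4)
  expect_true("SYN-07" %in% efaN$excluded)

  ## constant items make the correlation matrix undefined
  Xc <- scoreMatrix(fxClean$responses)
  Xc[, 3] <- 2L
  expect_error(efaScreen(ResponseMatrix(Xc)), "SYN-03")
})

test_that("Q3 residual correlations are symmetric, null-calm and sharp", {
  q3 <- q3Matrix(fxClean$responses, calClean$bank)
  M <- q3$q3
  expect_equal(M, t(M))
  ## locally independent data: no pair crosses 0.36, mean slightly negative
  expect_lt(max(M, na.rm = TRUE), 0.36)
  expect_lt(mean(M, na.rm = TRUE), 0)
  expect_equal(nrow(q3$flagged), 0L)

  ## a duplicated item with 10% noise produces a blatant Q3 signal
  desP <- syntheticDesign(nPersons = 1000L, nItems = 20L, seed = 604,
    defects = list(list(type = "dependent_pair", item = 8L,
                        partner = 9L, noise = 0.1)))
  fxP <- makeResponses(desP)
  calP <- calibrateGRM(fxP$responses)
  q3P <- q3Matrix(fxP$responses, calP$bank)
  expect_gt(q3P$q3["SYN-08", "SYN-09"], 0.36)
  expect_true(any(q3P$flagged$item_i == "SYN-08" &
                  q3P$flagged$item_j == "SYN-09"))
})

test_that("Q3 matches a direct residual-correlation computation", {
  ## independent oracle on a handful of pairs: residuals recomputed from
  ## first principles (expected score at the EAP estimate)
  rm <- fxClean$responses
  bank <- calClean$bank
  theta <- eapScore(bank, rm)$theta
  X <- scoreMatrix(rm)
  resid <- function(id) {
    p <- categoryProbs(bank, id, theta)     # n x 5
    X[, id] - as.numeric(p %*% (1:5))
  }
  q3 <- q3Matrix(rm, bank)
  for (pr in list(c(1, 2), c(5, 17), c(3, 11))) {
    i <- colnames(X)[pr[1]]; j <- colnames(X)[pr[2]]
    expect_equal(q3$q3[i, j], cor(resid(i), resid(j)), tolerance = 1e-12)
  }
})

test_that("Mokken scalability: Guttman data scales perfectly, noise not", {
  ## comonotone (perfect Guttman) polytomous data attains H = 1
  X <- matrix(rep(rep(1:5, each = 8), 3), ncol = 3)
  colnames(X) <- paste0("G", 1:3)
  expect_equal(mokkenScalability(ResponseMatrix(X))$H, 1)
  ## independent items hover near zero
  set.seed(42)
  Xr <- matrix(sample(1:5, 5000 * 10, TRUE), 5000, 10)
  colnames(Xr) <- paste0("R", 1:10)
  expect_lt(abs(mokkenScalability(ResponseMatrix(Xr))$H), 0.05)
  ## well-discriminating GRM data clears the 0.3 bar
  mok <- mokkenScalability(fxClean$responses)
  expect_gt(mok$H, 0.3)
  expect_length(mok$excluded, 0)
  ## degenerate input
  Xz <- Xr; Xz[, 2] <- 3L
  expect_error(mokkenScalability(ResponseMatrix(Xz)), "R2")
})

test_that("the summed-score recursion equals exhaustive enumeration", {
  bank <- tinyBank()
  grid <- quadratureGrid(21L, c(-3, 3))
  lw <- lordWingersky(bank, grid)
  combos <- as.matrix(expand.grid(1:5, 1:5, 1:5, 1:5))  # 625 patterns
  bf <- matrix(0, 17L, 21L)
  for (q in 1:21) {
    P <- vapply(1:4, function(j)
      categoryProbs(bank, j, grid@nodes[q]), numeric(5))
    for (r in seq_len(nrow(combos))) {
      s <- sum(combos[r, ] - 1L)
      bf[s + 1L, q] <- bf[s + 1L, q] + prod(P[cbind(combos[r, ], 1:4)])
    }
  }
  expect_equal(unname(lw), bf, tolerance = 1e-12)
  ## each column is a probability distribution
  expect_equal(colSums(lw), rep(1, 21), tolerance = 1e-12)
})

test_that("S-X2 keeps its size on model data and catches a wrong slope", {
  ## under a calibrated model the 1% test flags at most a sliver of items
  ft <- sx2ItemFit(fxClean$responses, calClean$bank)
  expect_true(all(!ft$untestable))
  expect_true(all(ft$df > 0))
  expect_lte(sum(ft$flagged), 1L)

  ## misfit power: responses from slope 3 scored against a slope-1 bank
  des <- cleanDesign(610)
  bank <- generateBank(des)
  it <- itemParameters(bank); it$a[7] <- 3.0
  rm <- generateResponses(ItemBank(it), generatePopulation(des), des)
  itW <- it; itW$a[7] <- 1.0
  ftW <- sx2ItemFit(rm, ItemBank(itW))
  expect_lt(ftW$p[7], 0.01)
})

test_that("ordinal-logistic DIF: quiet null, exact under duplication", {
  d0 <- difOrdinalLogistic(fxClean$responses, "gender", calClean$bank)
  expect_true(all(!d0$flagged))
  expect_lt(max(d0$deltaR2, na.rm = TRUE), 0.02)
  ## McFadden R2 matches a direct likelihood-ratio computation
  expect_true(all(d0$r2_m1 > 0 & d0$r2_m1 < 1, na.rm = TRUE))
  expect_true(all(d0$r2_m3 >= d0$r2_m1 - 1e-10, na.rm = TRUE))

  ## duplicating every person into both groups carries zero information
  X <- scoreMatrix(fxClean$responses)[1:400, ]
  Xd <- rbind(X, X)
  rownames(Xd) <- paste0("P", seq_len(nrow(Xd)))
  g <- rep(c("A", "B"), each = 400)
  rmD <- ResponseMatrix(Xd, personData = data.frame(grp = g))
  thetaD <- rep(eapScore(calClean$bank,
                         ResponseMatrix(X))$theta, 2)
  dD <- difOrdinalLogistic(rmD, "grp", calClean$bank, theta = thetaD)
  expect_lt(max(abs(dD$deltaR2), na.rm = TRUE), 1e-5)

  ## planted threshold shift of 0.8 for one group is flagged
  desD <- syntheticDesign(nPersons = 1000L, nItems = 20L, seed = 611,
    defects = list(list(type = "dif_item", item = 12L,
                        group = "gender", shift = 0.8)))
  fxD <- makeResponses(desD)
  calD <- calibrateGRM(fxD$responses)
  dP <- difOrdinalLogistic(fxD$responses, "gender", calD$bank)
  expect_gt(dP$deltaR2[12], 0.02)
  expect_true(dP$flagged[12])
  expect_error(
    difOrdinalLogistic(fxD$responses, "no_such_column", calD$bank),
    "not found")
})

test_that("the discrimination filter applies its strict 1.00 boundary", {
  expect_length(discriminationFilter(catIABank()), 0L)
  it <- itemParameters(tinyBank())  # T-4 has a = 0.9
  expect_equal(discriminationFilter(ItemBank(it)), "T-4")
  it$a[4] <- 0.99
  expect_equal(discriminationFilter(ItemBank(it)), "T-4")
  expect_length(
    discriminationFilter(ItemBank(it), qcThresholds(aMin = 1e-12)), 0L)
})

test_that("the QC pipeline passes clean data untouched and is idempotent", {
  rep1 <- runQCPipeline(fxClean$responses, groups = "gender")
  expect_equal(nrow(rep1$exclusions), 0L)
  expect_equal(rep1$iterations, 1L)
  expect_setequal(rep1$surviving, itemIds(fxClean$responses))
  ## fixed point: the pipeline on its own survivors excludes nothing
  again <- runQCPipeline(
    fxClean$responses[rep1$surviving, ], groups = "gender")
  expect_equal(nrow(again$exclusions), 0L)
})

test_that("planted defects are excluded and reason codes partition them", {
  fx <- makeResponses(plantedDesign(201))
  rep1 <- suppressWarnings(runQCPipeline(fx$responses, groups = "gender"))
  ex <- rep1$exclusions
  ## every dropped item carries exactly one reason code
  expect_false(any(duplicated(ex$item_id)))
  expect_true(all(ex$reason %in% c("unidimensionality", "local_dependence",
                                   "monotonicity", "dif", "item_fit",
                                   "discrimination")))
  expect_setequal(union(ex$item_id, rep1$surviving),
                  itemIds(fx$responses))
  ## the noise items fail the loading screen
  expect_true(all(c("SYN-03", "SYN-17") %in%
                  ex$item_id[ex$reason == "unidimensionality"]))
  ## exactly one member of the dependent pair leaves, for local dependence
  pairDrop <- intersect(c("SYN-08", "SYN-09"), ex$item_id)
  expect_length(pairDrop, 1L)
  expect_equal(ex$reason[ex$item_id == pairDrop], "local_dependence")
  ## the DIF item is caught by the DIF screen
  expect_equal(ex$reason[ex$item_id == "SYN-12"], "dif")
  ## the weak item is excluded (the loading screen reaches it first,
  ## before any discrimination estimate exists)
  expect_true("SYN-05" %in% ex$item_id)
})
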