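bank59 <- catIABank()

test_that("boundary probabilities follow the two-parameter logistic", {
  ## theta at the threshold gives exactly one half
  expect_equal(boundaryProb(bank59, "CIAT-81", -0.404, 1), 0.5)
  ## direct evaluation at theta = 0, k = 4 (a = 2.639, b4 = 2.407)
  expect_equal(boundaryProb(bank59, "CIAT-81", 0, 4),
               1 / (1 + exp(2.639 * 2.407)), tolerance = 1e-12)
  ## logistic limits
  expect_lt(boundaryProb(bank59, "IAT-3", -30, 1), 1e-10)
  expect_gt(boundaryProb(bank59, "IAT-3", 30, 4), 1 - 1e-10)
  ## strictly increasing in theta, decreasing in k
  th <- seq(-6, 6, by = 0.5)
  expect_true(all(diff(boundaryProb(bank59, "GAS-55", th, 2)) > 0))
  at0 <- vapply(1:4, function(k) boundaryProb(bank59, "GAS-55", 0, k),
                numeric(1))
  expect_true(all(diff(at0) < 0))
  expect_error(boundaryProb(bank59, "GAS-55", 0, 5), "k")
})

test_that("category probabilities are a proper distribution on all items", {
  th <- seq(-6, 6, by = 0.25)
  for (id in itemIds(bank59)) {
    P <- categoryProbs(bank59, id, th)
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, length(th)), tolerance = 1e-12)
  }
  ## boundary limit: deep below the bank everyone answers category 1
  expect_gt(categoryProbs(bank59, "CIAT-81", -10)[1], 0.999)
  ## middle categories are differences of adjacent boundary curves
  expect_equal(unname(categoryProbs(bank59, "CIAT-81", 0)[2]),
               boundaryProb(bank59, "CIAT-81", 0, 1) -
                 boundaryProb(bank59, "CIAT-81", 0, 2), tolerance = 1e-14)
})

test_that("expected item score increases strictly with theta", {
  th <- seq(-6, 6, by = 0.25)
  for (id in itemIds(bank59)[c(1, 10, 25, 43, 59)]) {
    es <- categoryProbs(bank59, id, th) %*% (1:5)
    expect_true(all(diff(as.numeric(es)) > 0))
  }
})

test_that("item information is non-negative, slope-sensitive and additive", {
  th <- seq(-6, 6, by = 0.25)
  for (id in itemIds(bank59))
    expect_true(all(itemInformation(bank59, id, th) >= 0))
  ## information vanishes far from the items
  expect_lt(itemInformation(bank59, "CIAT-81", 30), 1e-8)
  ## doubling the slope raises peak information
  it <- itemParameters(tinyBank())
  it2 <- it; it2$a <- it2$a * 2
  peak <- function(b, i) max(itemInformation(b, i, th))
  expect_gt(peak(ItemBank(it2), 1), peak(ItemBank(it), 1))
  ## a sharper item dominates a flatter one with comparable thresholds
  expect_gt(itemInformation(bank59, "CIAT-81", 1),
            itemInformation(bank59, "IAT-10", 1))
  ## test information is the sum over items and grows with the subset
  expect_equal(testInformation(bank59, 0.7, items = "GAS-65"),
               itemInformation(bank59, "GAS-65", 0.7))
  expect_equal(testInformation(bank59, 0),
               sum(vapply(itemIds(bank59), function(id)
                 itemInformation(bank59, id, 0), numeric(1))),
               tolerance = 1e-12)
  expect_gt(testInformation(bank59, -1.2),
            testInformation(bank59, -1.2, items = itemIds(bank59)[1:30]))
  expect_error(testInformation(tinyBank()[1], 0, items = character(0)))
})

test_that("pattern log-likelihood telescopes and ignores item order", {
  expect_equal(logLikelihood(bank59, character(0), integer(0), 0.3), 0)
  expect_equal(logLikelihood(bank59, "IAT-6", 4L, -0.2),
               unname(log(categoryProbs(bank59, "IAT-6", -0.2)[4])))
  ids <- c("CIAT-81", "IAT-3", "GAS-70", "GPIUS-44")
  sc <- c(4L, 2L, 1L, 5L)
  perm <- c(3, 1, 4, 2)
  expect_identical(logLikelihood(bank59, ids, sc, 0.9),
                   logLikelihood(bank59, ids[perm], sc[perm], 0.9))
  expect_error(logLikelihood(bank59, "NOPE-1", 3L, 0), "unknown")
})

test_that("fit indices follow the AIC/BIC arithmetic", {
  f <- fitIndices(100, 10, exp(1))
  expect_equal(f$AIC, 120)
  expect_equal(f$BIC, 110)
  expect_error(fitIndices(0, 0, 10), "nParams")
  ## BIC exceeds AIC once log(N) > 2
  expect_gt(fitIndices(50, 3, 10)$BIC, fitIndices(50, 3, 10)$AIC)
  expect_lt(fitIndices(50, 3, 5)$BIC, fitIndices(50, 3, 5)$AIC)
})

test_that("EAP matches a dense-grid posterior oracle and the prior", {
  e0 <- eapEstimate(bank59, character(0), integer(0))
  expect_equal(e0@theta, 0, tolerance = 0.01)
  expect_equal(e0@se, 1, tolerance = 0.01)
  expect_equal(e0@nItemsUsed, 0L)
  ## uniformly extreme responses push the estimate beyond 2
  eHi <- eapEstimate(bank59, itemIds(bank59), rep(5L, 59))
  expect_gt(eHi@theta, 2)
  ## dense-grid oracle agreement on random patterns
  set.seed(101)
  for (i in 1:20) {
    k <- sample(59, sample(2:25, 1))
    ids <- itemIds(bank59)[k]
    sc <- sample(1:5, length(k), replace = TRUE)
    est <- eapEstimate(bank59, ids, sc)
    orc <- oracleEAP(bank59, ids, sc)
    expect_equal(est@theta, orc$theta, tolerance = 1e-4)
    expect_equal(est@se, orc$se, tolerance = 1e-4)
  }
})

test_that("EAP is bit-for-bit invariant to administration order", {
  set.seed(7)
  k <- sample(59, 15)
  ids <- itemIds(bank59)[k]
  sc <- sample(1:5, 15, replace = TRUE)
  ref <- eapEstimate(bank59, ids, sc)
  for (r in 1:5) {
    p <- sample(15)
    alt <- eapEstimate(bank59, ids[p], sc[p])
    expect_identical(alt@theta, ref@theta)
    expect_identical(alt@se, ref@se)
  }
})

test_that("simulated responses are seed-stable and match the model", {
  th <- rep(-10, 200)
  rm <- simulateResponses(bank59, th, seed = 5)
  expect_gt(mean(scoreMatrix(rm) == 1L), 0.99)
  rm2 <- simulateResponses(bank59, th, seed = 5)
  expect_identical(scoreMatrix(rm), scoreMatrix(rm2))
  ## empirical category frequencies at fixed theta vs model probabilities
  n <- 10000
  rm3 <- simulateResponses(bank59[c("CIAT-84", "IAT-12")],
                           rep(0.4, n), seed = 11)
  for (id in c("CIAT-84", "IAT-12")) {
    p <- categoryProbs(bank59, id, 0.4)
    obs <- tabulate(scoreMatrix(rm3)[, id], 5) / n
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(obs - p) <= 3 * se + 1e-9))
  }
})

test_that("full-pattern vectorized scoring agrees with single calls", {
  set.seed(13)
  rm <- simulateResponses(bank59, rnorm(25), seed = 21)
  sc <- eapScore(bank59, rm)
  X <- scoreMatrix(rm)
  for (p in c(1, 9, 25)) {
    e <- eapEstimate(bank59, colnames(X), unname(X[p, ]))
    expect_equal(sc$theta[p], e@theta, tolerance = 1e-10)
    expect_equal(sc$se[p], e@se, tolerance = 1e-10)
  }
})
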