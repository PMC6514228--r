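test_that("conditional error indices obey their algebraic identities", {
  th <- seq(-2, 2, length.out = 101)
  ## perfect estimation: all error indices vanish
  cs <- conditionalStats(th, th, rep(0.2, 101))
  expect_equal(unname(cs$overall[c("cbias", "cmae", "crmse")]), c(0, 0, 0))
  expect_equal(unname(cs$overall["csee"]), 0.2)
  ## constant shift: all three error indices equal the shift
  cs2 <- conditionalStats(th, th + 0.1, rep(0.2, 101))
  expect_equal(unname(cs2$overall[c("cbias", "cmae", "crmse")]),
               c(0.1, 0.1, 0.1), tolerance = 1e-12)
  ## CRMSE >= CMAE >= |CBIAS| in every non-empty bin and overall
  set.seed(8)
  tt <- rnorm(500); est <- tt + rnorm(500, 0, 0.3)
  cs3 <- conditionalStats(tt, est, runif(500, 0.1, 0.4))
  expect_gte(cs3$overall["crmse"], cs3$overall["cmae"])
  expect_gte(cs3$overall["cmae"], abs(cs3$overall["cbias"]))
  bb <- cs3$byBin[cs3$byBin$n > 0, ]
  expect_true(all(bb$crmse >= bb$cmae - 1e-12))
  expect_true(all(bb$cmae >= abs(bb$cbias) - 1e-12))
  ## empty bins are reported as missing, not zero
  expect_true(all(is.na(cs3$byBin[cs3$byBin$n == 0,
                                  c("cbias", "cmae", "crmse", "csee")])))
  ## the overall row is the person-level mean, not a mean of bin means
  expect_equal(unname(cs3$overall["cbias"]), mean(est - tt))
})

test_that("marginal reliability reproduces the printed arithmetic", {
  expect_equal(round(marginalReliability(rep(0.159, 7)), 3), 0.975)
  expect_equal(round(marginalReliability(rep(0.293, 7)), 3), 0.914)
  expect_equal(marginalReliability(rep(0, 5)), 1)
  ## mean-then-square, not square-then-mean
  ses <- c(0.1, 0.5)
  expect_equal(marginalReliability(ses), 1 - 0.3^2)
})

test_that("item savings and cross-rule agreement summarize a sweep", {
  base <- data.frame(theta = c(-1, 0, 1, 2), se = rep(0.2, 4),
                     n_items = rep(59, 4))
  short <- data.frame(theta = c(-1.1, 0.2, 0.9, 2.2),
                      se = rep(0.45, 4), n_items = rep(27.655, 4))
  out <- savingsAndCorrelations(list(none = base, short = short), 59)
  self <- out[out$rule == "none", ]
  expect_equal(self$r, 1)
  expect_equal(self$savings_pct, 0)
  ## the printed savings figure: 27.655 of 59 items is 53.1% saved
  expect_equal(round(out$savings_pct[out$rule == "short"], 1), 53.1)
  expect_error(
    savingsAndCorrelations(list(none = base, short = short[1:3, ]), 59),
    "same persons")
})

test_that("concurrent validity behaves like a Pearson correlation", {
  bank <- catIABank()
  rm <- simulateResponses(bank, rnorm(300), seed = 55)
  sc <- eapScore(bank, rm)
  ## estimates correlate strongly with the monotone sum-score proxy
  total <- rowSums(scoreMatrix(rm))
  expect_gt(cor(sc$theta, total), 0.9)
  cv <- concurrentValidity(sc$theta, rm)
  expect_setequal(cv$scale, c("IAT", "GPIUS", "GAS", "CIAT"))
  expect_true(all(cv$r > 0.5))
  expect_true(all(cv$p < 0.01))
  ## correlation is invariant to a linear rescaling of the estimates
  cv2 <- concurrentValidity(3 + 2 * sc$theta, rm)
  expect_equal(cv2$r, cv$r, tolerance = 1e-12)
  ## an estimate equal to a z-scored sum correlates perfectly
  iat <- grep("^IAT", colnames(scoreMatrix(rm)), value = TRUE)
  z <- scale(rowSums(scoreMatrix(rm)[, iat]))[, 1]
  cvz <- concurrentValidity(z, rm)
  expect_equal(cvz$r[cvz$scale == "IAT"], 1, tolerance = 1e-12)
})

test_that("AUC equals the pairwise-enumeration oracle and known limits", {
  ## perfectly separated classes
  sep <- rocPredictiveValidity(c(1:5, 11:15),
                               rep(c(FALSE, TRUE), each = 5))
  expect_equal(sep$auc, 1)
  expect_equal(sep$youden, 1)
  expect_gt(sep$cutoff, 5); expect_lt(sep$cutoff, 11)
  ## exact agreement with brute-force pair counting, ties included
  set.seed(19)
  for (r in 1:5) {
    pred <- sample(1:8, 60, replace = TRUE)  # heavy ties
    lab <- runif(60) < 0.4
    if (!any(lab) || all(lab)) next
    expect_identical(rocPredictiveValidity(pred, lab)$auc,
                     oracleAUC(pred, lab))
  }
  ## labels independent of the predictor: AUC near 1/2
  set.seed(23)
  predN <- rnorm(2000); labN <- runif(2000) < 0.5
  n1 <- sum(labN); n0 <- sum(!labN)
  seNull <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(rocPredictiveValidity(predN, labN)$auc - 0.5),
            3 * seNull)
  ## agreement with an established ROC implementation
  pr <- suppressMessages(pROC::roc(labN, predN, quiet = TRUE,
                                   direction = "<"))
  expect_equal(rocPredictiveValidity(predN, labN)$auc,
               as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_error(rocPredictiveValidity(1:5, rep(TRUE, 5)), "both classes")
})

test_that("Youden maximization reports a coherent operating point", {
  set.seed(29)
  pred <- c(rnorm(300, 0), rnorm(120, 1.4))
  lab <- rep(c(FALSE, TRUE), c(300, 120))
  r <- rocPredictiveValidity(pred, lab)
  expect_equal(r$youden, r$sensitivity + r$specificity - 1)
  expect_true(r$auc >= 0 && r$auc <= 1)
  expect_true(all(c(r$sensitivity, r$specificity) >= 0))
  expect_true(all(c(r$sensitivity, r$specificity) <= 1))
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  ## the DeLong variance option yields a similar interval
  rd <- rocPredictiveValidity(pred, lab, ciMethod = "delong")
  expect_equal(rd$auc, r$auc)
  expect_equal(rd$ci, r$ci, tolerance = 0.02)
})

test_that("diagnostic rules implement their strict boundaries", {
  X <- matrix(1L, 3, 20, dimnames = list(NULL, paste0("IAT-", 1:20)))
  X[2, ] <- 2L                 # sum 40: exceeds 39
  X[3, 1:19] <- 2L             # sum 39: boundary, NOT positive
  rm <- ResponseMatrix(X)
  iat <- diagnosticRule("sum", paste0("IAT-", 1:20), sumCut = 39)
  expect_identical(unname(applyDiagnosticRule(rm, iat)),
                   c(FALSE, TRUE, FALSE))

  G <- matrix(1L, 2, 7, dimnames = list(NULL, paste0("GAS-", 1:7)))
  G[1, 1:4] <- 5L              # four items at >= 4: positive
  G[2, 1:3] <- 5L              # only three: negative
  rmG <- ResponseMatrix(G)
  gas <- diagnosticRule("count", paste0("GAS-", 1:7),
                        scoreCut = 4, countCut = 4)
  expect_identical(unname(applyDiagnosticRule(rmG, gas)),
                   c(TRUE, FALSE))
  expect_error(
    applyDiagnosticRule(rmG, diagnosticRule("count", "GAS-99")),
    "GAS-99")
})
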