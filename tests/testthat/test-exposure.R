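test_that("exposure degrees partition doses with sham isolated at zero", {
  ed <- assignED(c(0, 0.05, 0.1, 0.5, 1))
  expect_identical(as.character(ed), c("ED0", "ED1", "ED1", "ED2", "ED2"))
  expect_true(is.ordered(ed))
  expect_error(assignED(c(0, 3)), "above the top break")
  expect_error(assignED(-1), ">= 0")
  custom <- assignED(c(0, 0.2, 1.5, 4), breaks = c(0.5, 2, 5))
  expect_identical(as.character(custom), c("ED0", "ED1", "ED2", "ED3"))
})

test_that("OLS fitting recovers exact and generating coefficients", {
  # two points, one predictor: exact interpolation
  m <- fitERS(data.frame(x = c(0, 1)), c(0, 1))
  expect_equal(modelIntercept(m), 0)
  expect_equal(unname(modelCoefficients(m)), 1)

  # noise-free responses generated from the carbon-ion coefficients
  fix <- ersModel("carbon")
  set.seed(99)
  X <- as.data.frame(matrix(runif(40 * 5), 40, 5,
                            dimnames = list(NULL, markerIds(fix))))
  y <- scoreERS(fix, X)
  fit <- fitERS(X, y, radiationType = "carbon")
  expect_equal(modelIntercept(fit), modelIntercept(fix), tolerance = 1e-8)
  expect_equal(modelCoefficients(fit), modelCoefficients(fix),
               tolerance = 1e-8)

  # constant predictor is rejected by name
  Xc <- cbind(X, bad = 1)
  expect_error(fitERS(Xc, y), "bad")

  # collinear predictors are rejected by name
  Xd <- X
  Xd$dup <- X[[1]] * 2
  expect_error(fitERS(Xd, y), "rank-deficient.*dup")
})

test_that("coefficient noise shrinks with sample size", {
  fix <- ersModel("proton")
  rmse <- vapply(c(50, 500), function(n) {
    set.seed(n)
    X <- as.data.frame(matrix(runif(n * 5), n, 5,
                              dimnames = list(NULL, markerIds(fix))))
    y <- scoreERS(fix, X) + rnorm(n, 0, 0.3)
    fit <- fitERS(X, y)
    sqrt(mean((modelCoefficients(fit) - modelCoefficients(fix))^2))
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
})

test_that("fixture models score exactly as printed linear equations", {
  carbon <- ersModel("carbon")
  xray <- ersModel("xray")
  proton <- ersModel("proton")
  expect_identical(length(markerIds(carbon)), 5L)
  expect_identical(length(markerIds(xray)), 4L)

  expect_equal(scoreERS(carbon, rep(0, 5)), 0.646)
  expect_equal(scoreERS(xray, rep(0, 4)), 0.943)
  expect_equal(scoreERS(proton, rep(0, 5)), 0.521)
  expect_equal(scoreERS(carbon, rep(1, 5)), 0.359)
  expect_equal(scoreERS(proton, rep(1, 5)), 0.428)

  expect_error(scoreERS(carbon, rep(0, 4)), "expected 5")
  expect_error(scoreERS(carbon, c(a = 1, b = 2, c = 3, d = 4, e = 5)),
               "missing marker")

  # named vectors are reordered to the model's marker order
  x <- stats::setNames(c(1, 0, 0, 0, 0), rev(markerIds(carbon)))
  expect_equal(scoreERS(carbon, x), 0.646 - 0.206)
})

test_that("scoring is exactly linear in the markers", {
  m <- ersModel("carbon")
  set.seed(1)
  for (i in 1:20) {
    x <- runif(5); y <- runif(5)
    expect_equal(scoreERS(m, x + y) - scoreERS(m, x) - scoreERS(m, y) +
                   modelIntercept(m), 0, tolerance = 1e-12)
  }
})

test_that("model JSON round-trips", {
  m <- ersModel("xray")
  f <- withr::local_tempfile(fileext = ".json")
  writeERSModel(m, f)
  back <- readERSModel(f)
  expect_identical(markerIds(back), markerIds(m))
  expect_equal(modelIntercept(back), modelIntercept(m))
  expect_equal(modelCoefficients(back), modelCoefficients(m))
})

test_that("ROC handles separable, partially ordered and degenerate score sets", {
  expect_equal(auc(rocCurve(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))), 1)
  expect_equal(auc(rocCurve(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1))), 0.75)
  expect_equal(auc(rocCurve(rep(1, 6), c(0, 1, 0, 1, 0, 1))), 0.5)
  expect_error(rocCurve(1:4, c(1, 1, 1, 1)), "both classes")

  r <- rocCurve(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(r@sensitivity, 1)
  expect_equal(r@specificity, 1)
  # suppressed marker read with lower-is-positive: same AUC as negation
  expect_equal(auc(rocCurve(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1), "lower")), 1)
})

test_that("trapezoidal AUC equals Mann-Whitney concordance on 1000 fuzz cases", {
  set.seed(2024)
  for (i in 1:1000) {
    n <- sample(4:20, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    # ties are common on a coarse grid
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    r <- rocCurve(scores, labels)
    expect_equal(auc(r), oracleConcordance(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(r@tpr) >= 0) && all(diff(r@fpr) >= 0))
    expect_true(all(r@tpr >= 0 & r@tpr <= 1) && all(r@fpr >= 0 & r@fpr <= 1))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(7)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4)
  a0 <- auc(rocCurve(scores, labels))
  expect_equal(auc(rocCurve(exp(scores), labels)), a0)
  expect_equal(auc(rocCurve(5 * scores - 3, labels)), a0)
  expect_equal(auc(rocCurve(atan(scores), labels)), a0)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- c(rnorm(25, 1), rnorm(30, 0))
  labels <- c(rep(1, 25), rep(0, 30))
  ours <- auc(rocCurve(scores, labels))
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("panel-vs-single comparison flags the winner and orients suppressed markers", {
  # one perfect marker: its AUC and the panel's are both 1
  set.seed(55)
  labels <- rep(c(0, 1), each = 10)
  X <- data.frame(perfect = labels + runif(20, 0, 0.4),
                  noise1 = rnorm(20), noise2 = rnorm(20))
  m <- fitERS(X, labels)
  cmp <- comparePanelVsSingle(m, X, labels)
  expect_equal(cmp$auc[cmp$predictor == "perfect"], 1)
  expect_equal(cmp$auc[cmp$predictor == "panel"], 1)
  expect_true(attr(cmp, "panel_is_max"))

  # pure-noise markers hover near 0.5
  set.seed(56)
  Xn <- as.data.frame(matrix(rnorm(20 * 3), 20, 3))
  names(Xn) <- c("a", "b", "c")
  labN <- rep(c(0, 1), 10)
  mN <- fitERS(Xn, labN)
  cmpN <- comparePanelVsSingle(mN, Xn, labN)
  singles <- cmpN$auc[cmpN$predictor != "panel"]
  expect_true(all(singles >= 0.35 & singles <= 0.65 |
                    singles >= 0.5))  # oriented AUCs sit at or above 0.5
  # suppressed markers are oriented lower-is-positive
  Xs <- data.frame(down = -labels + rnorm(20, 0, 0.3))
  ms <- fitERS(Xs, labels)
  cs <- comparePanelVsSingle(ms, Xs, labels)
  expect_identical(cs$direction[cs$predictor == "down"], "lower")
  expect_gt(cs$auc[cs$predictor == "down"], 0.9)
})

test_that("weak correlated markers: the fitted panel dominates singles in most replicates", {
  wins <- 0
  for (seed in 1:40) {
    set.seed(seed)
    n <- 30
    ed <- rep(0:2, each = n / 3)
    X <- as.data.frame(vapply(1:5, function(j)
      -0.25 * ed + rnorm(n, 0, 0.45), numeric(n)))
    names(X) <- paste0("m", 1:5)
    m <- fitERS(X, ed)
    cmp <- comparePanelVsSingle(m, X, as.integer(ed > 0))
    if (attr(cmp, "panel_is_max")) wins <- wins + 1
  }
  expect_gte(wins / 40, 0.9)
})
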