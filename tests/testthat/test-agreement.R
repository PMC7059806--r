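randomTable <- function(seed) {
  set.seed(seed)
  matrix(rpois(9, lambda = sample(1:6, 1)), 3, 3)
}

test_that("weighted kappa reproduces the hand-evaluated reference table", {
  tab <- rbind(c(2, 1, 0), c(1, 2, 1), c(0, 1, 2))  # n = 10
  # linear weights: p_o,w = 0.80, p_e,w = 0.58 -> kappa = 0.22/0.42
  expect_equal(weightedKappaFromTable(tab, "linear"), 0.22 / 0.42,
               tolerance = 1e-12)
  expect_equal(weightedKappaFromTable(tab, "linear"), 0.5238, tolerance = 1e-4)
})

test_that("perfect agreement on a non-constant vector gives kappa 1", {
  a <- asRating(c("OK", "Maybe", "Fail", "OK", "Maybe"))
  expect_equal(weightedKappa(a, a), 1)
  expect_equal(weightedKappa(a, a, "quadratic"), 1)
  expect_equal(weightedKappa(a, a, "unweighted"), 1)
})

test_that("vectorized kappa equals the scalar-loop oracle on random tables", {
  for (seed in 1:60) {
    tab <- randomTable(seed)
    if (sum(tab) == 0) next
    for (w in c("linear", "quadratic", "unweighted")) {
      want <- oracleKappa(tab, w)
      got <- weightedKappaFromTable(tab, w)
      if (is.na(want)) expect_true(is.na(got))
      else expect_equal(as.numeric(got), want, tolerance = 1e-12)
    }
  }
})

test_that("kappa is symmetric and undefined exactly when p_e = 1", {
  set.seed(5)
  a <- asRating(sample(ratingLevels(), 30, replace = TRUE))
  b <- asRating(sample(ratingLevels(), 30, replace = TRUE))
  expect_equal(weightedKappa(a, b), weightedKappa(b, a))

  const <- asRating(rep("OK", 10))
  und <- weightedKappa(const, const)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))

  expect_error(weightedKappa(a[1], b[1]), "fewer than 2")
  expect_error(weightedKappa(unname(a), unname(b[1:10])), "differ in length")
})

test_that("independent raters drift to kappa 0 at large n", {
  set.seed(99)
  a <- asRating(sample(ratingLevels(), 6000, replace = TRUE, prob = c(2, 3, 5)))
  b <- asRating(sample(ratingLevels(), 6000, replace = TRUE, prob = c(2, 3, 5)))
  expect_lt(abs(weightedKappa(a, b)), 0.05)
})

test_that("named vectors are paired on their common images only", {
  a <- asRating(c(i1 = "OK", i2 = "Maybe", i3 = "Fail", i4 = "OK"))
  b <- asRating(c(i2 = "Maybe", i3 = "Fail", i4 = "OK", i9 = "Fail"))
  expect_equal(weightedKappa(a, b), 1)  # the 3 shared images agree exactly
})

test_that("per-category Dice follows the set formula", {
  a <- asRating(c(i1 = "OK", i2 = "OK", i3 = "OK", i4 = "Fail"))
  b <- asRating(c(i1 = "OK", i2 = "OK", i3 = "OK", i4 = "Fail"))
  expect_equal(categoryDice(a, b, "OK"), 1)

  # X = {a,b,c}, Y = {b,c,d}: 2*2 / (3+3)
  a2 <- asRating(c(a = "OK", b = "OK", c = "OK", d = "Maybe"))
  b2 <- asRating(c(a = "Maybe", b = "OK", c = "OK", d = "OK"))
  expect_equal(categoryDice(a2, b2, "OK"), 2 / 3, tolerance = 1e-12)
  expect_equal(categoryDice(a2, b2, "OK"), categoryDice(b2, a2, "OK"))

  # disjoint non-empty sets
  a3 <- asRating(c(x = "OK", y = "Maybe"))
  b3 <- asRating(c(x = "Maybe", y = "OK"))
  expect_equal(categoryDice(a3, b3, "OK"), 0)

  und <- categoryDice(a3, b3, "Fail")  # neither rater used Fail
  expect_true(is.na(und) && attr(und, "undefined"))
})

test_that("Landis-Koch bands follow the upper-closed convention", {
  expect_identical(interpretStrength(0.54), "moderate")
  expect_identical(interpretStrength(0), "poor")
  expect_identical(interpretStrength(0.80), "substantial")
  expect_identical(interpretStrength(-1), "poor")
  expect_identical(interpretStrength(0.005), "slight")
  expect_identical(interpretStrength(1), "almost perfect")
  expect_identical(interpretStrength(c(0.2, 0.21)), c("slight", "fair"))
  expect_error(interpretStrength(1.2), "\\[-1, 1\\]")
})

test_that("the pairwise report matches per-pair direct computation", {
  set.seed(8)
  truth <- sample(ratingLevels(), 60, replace = TRUE, prob = c(.35, .35, .30))
  tab <- simulateRatings(truth, honestPool(9, seed = 2), seed = 77)
  rep_ <- pairwiseReport(tab)
  rid <- raterIds(tab)
  expect_identical(rep_@units, rid)
  expect_equal(diag(rep_@kappa), rep(1, 9), ignore_attr = TRUE)
  for (pair in list(c(1, 2), c(3, 7), c(8, 9))) {
    a <- raterVector(tab, rid[pair[1]]); b <- raterVector(tab, rid[pair[2]])
    expect_equal(rep_@kappa[pair[1], pair[2]],
                 as.numeric(weightedKappa(a, b)))
    expect_equal(rep_@kappa[pair[1], pair[2]], rep_@kappa[pair[2], pair[1]])
    for (l in ratingLevels())
      expect_equal(rep_@dice[[l]][pair[1], pair[2]],
                   as.numeric(categoryDice(a, b, l)))
    expect_identical(rep_@bands[pair[1], pair[2]],
                     interpretStrength(rep_@kappa[pair[1], pair[2]]))
    expect_identical(rep_@nCommon[pair[1], pair[2]], 60L)
  }
})

test_that("panels can be compared against individual raters in one report", {
  set.seed(12)
  truth <- sample(ratingLevels(), 50, replace = TRUE)
  tab <- simulateRatings(truth, honestPool(9, seed = 5), seed = 13)
  rid <- raterIds(tab)
  units <- c(list(Ec = rid), as.list(stats::setNames(rid[1:3], rid[1:3])))
  rep_ <- pairwiseReport(tab, units)
  expect_identical(rep_@units, c("Ec", rid[1:3]))
  cons <- suppressWarnings(panelConsensus(tab, rid))
  expect_equal(rep_@kappa["Ec", rid[1]],
               as.numeric(weightedKappa(cons, raterVector(tab, rid[1]))))
})

test_that("pairs with too little overlap are flagged NA, not fatal", {
  tab <- RatingTable(c("i1", "i2", "i1"), c("A", "A", "B"),
                     c("OK", "Fail", "Maybe"))
  rep_ <- pairwiseReport(tab, c("A", "B"))
  expect_true(is.na(rep_@kappa["A", "B"]))
  expect_identical(rep_@nCommon["A", "B"], 1L)
})
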