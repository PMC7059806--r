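studyMargins <- c(0.30, 0.35, 0.35)

test_that("worst-case variance equals the vertex-enumeration oracle", {
  for (kap in c(0.5, 0.72)) {
    want <- oracleMaxKappaVariance(studyMargins, studyMargins, kap)
    expect_equal(kappaVariance(studyMargins, kappa = kap), want,
                 tolerance = 1e-9, label = sprintf("kappa=%g", kap))
  }
  # asymmetric margins
  pa <- c(0.2, 0.3, 0.5); pb <- c(0.4, 0.35, 0.25)
  for (kap in c(0.1, 0.45))
    expect_equal(kappaVariance(pa, pb, kappa = kap),
                 oracleMaxKappaVariance(pa, pb, kap), tolerance = 1e-9)
})

test_that("the extremal joint has the requested margins and kappa", {
  J <- extremalJoint(studyMargins, kappa = 0.72)
  expect_equal(rowSums(J), studyMargins, tolerance = 1e-9)
  expect_equal(colSums(J), studyMargins, tolerance = 1e-9)
  pe <- sum(studyMargins^2)
  expect_equal(sum(diag(J)), 0.72 * (1 - pe) + pe, tolerance = 1e-9)
  expect_true(all(J >= -1e-12))
})

test_that("perfect agreement with equal margins has no sampling variability", {
  expect_equal(kappaVariance(studyMargins, kappa = 1), 0, tolerance = 1e-9)
})

test_that("variance is invariant under swapping the raters", {
  pa <- c(0.25, 0.35, 0.40); pb <- c(0.30, 0.45, 0.25)
  expect_equal(kappaVariance(pa, pb, kappa = 0.6),
               kappaVariance(pb, pa, kappa = 0.6), tolerance = 1e-9)
})

test_that("unattainable kappas raise a feasibility error", {
  # near-disjoint margins cap the diagonal far below what kappa = 0.9 needs
  pa <- c(0.9, 0.05, 0.05); pb <- c(0.05, 0.9, 0.05)
  expect_error(kappaVariance(pa, pb, kappa = 0.9), "unattainable")
  expect_error(extremalJoint(pa, pb, kappa = 0.9), "unattainable")
})

test_that("scenario validation enforces k0 < k1 and proper probabilities", {
  expect_error(kappaPowerScenario(studyMargins, k0 = 0.5, k1 = 0.5),
               "k0 < k1")
  expect_error(kappaPowerScenario(studyMargins, k0 = 0.7, k1 = 0.5),
               "k0 < k1")
  expect_error(kappaPowerScenario(c(0.5, 0.4), k0 = 0, k1 = 0.5), "sum to 1")
  expect_error(kappaPowerScenario(studyMargins, k0 = 0, k1 = 0.5, alpha = 2),
               "alpha")
})

test_that("minimum sample size moves the right way with power, effect and alpha", {
  n <- function(...) minSampleSize(kappaPowerScenario(studyMargins, k0 = 0.5,
                                                      k1 = 0.72, ...))
  expect_gt(n(power = 0.9), n(power = 0.8))
  expect_gt(n(alpha = 0.01), n(alpha = 0.05))
  wide <- minSampleSize(kappaPowerScenario(studyMargins, k0 = 0.5, k1 = 0.85))
  expect_lt(wide, n(power = 0.8))
  two <- minSampleSize(kappaPowerScenario(studyMargins, k0 = 0.5, k1 = 0.72,
                                          sided = "two_sided"))
  expect_gt(two, n(power = 0.8))
  expect_identical(minSampleSize(kappaPowerScenario(studyMargins, k0 = 0.5,
                                                    k1 = 0.72)),
                   minSampleSize(kappaPowerScenario(rev(studyMargins),
                                                    k0 = 0.5, k1 = 0.72)))
})

test_that("empirical power is seeded, monotone in n, and near alpha under tiny effects", {
  sc <- kappaPowerScenario(studyMargins, k0 = 0.5, k1 = 0.72)
  p1 <- empiricalPower(sc, n = 30, reps = 500, seed = 42)
  expect_identical(as.numeric(p1),
                   as.numeric(empiricalPower(sc, n = 30, reps = 500, seed = 42)))
  pBig <- empiricalPower(sc, n = 150, reps = 500, seed = 42)
  expect_gt(pBig, p1)
  # far below the computed minimum the power cannot reach the target
  expect_lt(empiricalPower(sc, n = 5, reps = 1000, seed = 7), 0.8)
  # k1 barely above k0: rejection rate collapses to the test's size
  null <- kappaPowerScenario(studyMargins, k0 = 0.5, k1 = 0.501)
  expect_lt(empiricalPower(null, n = 40, reps = 1000, seed = 3), 0.12)
})

test_that("the simplex solver handles a known transportation optimum", {
  # max x11 + x22 with margins (0.6, 0.4) both ways: optimum 1 at diag
  A <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 1, 0, 0), c(0, 0, 1, 1))
  sol <- regqc:::simplexMax(c(1, 0, 0, 1), A, c(0.6, 0.4, 0.6, 0.4))
  expect_true(sol$feasible)
  expect_equal(sol$value, 1, tolerance = 1e-9)
  # infeasible system
  bad <- regqc:::simplexMax(c(1, 0), rbind(c(1, 1), c(1, 1)), c(1, 2))
  expect_false(bad$feasible)
})
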