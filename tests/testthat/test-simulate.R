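test_that("phantoms are deterministic per seed and anatomically plausible", {
  a <- generatePhantom(seed = 5, shape = c(24, 28, 24))
  b <- generatePhantom(seed = 5, shape = c(24, 28, 24))
  expect_identical(volumeData(a$template), volumeData(b$template))
  expect_identical(volumeData(a$mask), volumeData(b$mask))
  expect_false(identical(volumeData(a$template),
                         volumeData(generatePhantom(seed = 6,
                                                    shape = c(24, 28, 24))$template)))
  m <- volumeData(a$mask)
  expect_gt(sum(m), 0)
  expect_true(all(m %in% c(0, 1)))
  expect_true(isConnectedMask(m))
  expect_true(gridCompatible(a$template, a$mask))
  # default grid covers the protocol's slice coordinates
  ph <- generatePhantom(seed = 1)
  for (i in seq_len(nrow(sliceProtocol())))
    expect_no_error(extractSlicePlane(ph$template, sliceProtocol()$axis[i],
                                      sliceProtocol()$mm[i]))
  expect_error(generatePhantom(seed = 1, shape = c(8, 24, 24)), "at least 16")
})

test_that("the phantom's outline shell is about 8 mm thick at 1 mm resolution", {
  ph <- generatePhantom(seed = 2, shape = c(48, 48, 48), voxelMm = 1)
  shell <- buildOutlineShell(ph$mask, 4, 4)
  d2in <- regqc:::squaredEDT(volumeData(ph$mask) != 0, c(1, 1, 1))
  d2out <- regqc:::squaredEDT(volumeData(ph$mask) == 0, c(1, 1, 1))
  sh <- volumeData(shell) != 0
  # every shell voxel lies within 4 mm of the outline on either side
  expect_lte(max(sqrt(d2in[sh & volumeData(ph$mask) == 0])), 4 + 1)
  expect_lte(max(sqrt(d2out[sh & volumeData(ph$mask) == 1])), 4 + 1)
  # and the shell straddles the outline with ~8 mm of material
  expect_gt(max(sqrt(d2in[sh])) + max(sqrt(d2out[sh])), 8 - 1)
})

test_that("registration perturbations respect the displacement bound", {
  n <- 40L
  g <- coordGrids(n, 1)
  aff <- centredAffine(rep(n, 3L), c(1, 1, 1))
  maxD <- 6
  for (axis in 1:3) {
    lin <- BrainVolume(g[[c("X", "Y", "Z")[axis]]], aff)
    out <- perturbRegistration(lin, maxD, seed = 11)
    interior <- abs(g$X) < (n - 1) / 2 - maxD - 1 &
                abs(g$Y) < (n - 1) / 2 - maxD - 1 &
                abs(g$Z) < (n - 1) / 2 - maxD - 1
    # trilinear sampling of a linear coordinate field returns the displaced
    # coordinate exactly, so the intensity change reads out the field
    shift <- abs(volumeData(out) - volumeData(lin))[interior]
    expect_lte(max(shift), maxD + 1e-6)
  }
  ph <- generatePhantom(seed = 3, shape = c(24, 24, 24))
  expect_identical(perturbRegistration(ph$template, 0, seed = 1), ph$template)
  p1 <- perturbRegistration(ph$template, 8, seed = 1)
  p2 <- perturbRegistration(ph$template, 8, seed = 2)
  expect_false(identical(volumeData(p1), volumeData(p2)))
})

test_that("identity raters reproduce the truth and agree perfectly", {
  truth <- c(a = "Fail", b = "Maybe", c = "OK", d = "Maybe", e = "OK")
  ident <- lapply(1:3, function(i) raterProfile(paste0("P", i), diag(3)))
  tab <- simulateRatings(truth, ident, seed = 2)
  for (r in raterIds(tab))
    expect_identical(as.character(raterVector(tab, r)[names(truth)]),
                     unname(as.character(asRating(truth))))
  rep_ <- pairwiseReport(tab)
  expect_equal(rep_@kappa[upper.tri(rep_@kappa)], rep(1, 3))
})

test_that("coin-flip raters show no agreement at large n", {
  set.seed(1)
  truth <- sample(ratingLevels(), 2500, replace = TRUE)
  unif <- lapply(1:2, function(i)
    raterProfile(paste0("U", i), matrix(1 / 3, 3, 3)))
  tab <- simulateRatings(truth, unif, seed = 8)
  k <- weightedKappa(raterVector(tab, "U1"), raterVector(tab, "U2"))
  expect_lt(abs(k), 0.06)
})

test_that("simulated kappa is calibrated against the closed-form value", {
  prev <- c(Fail = 0.35, Maybe = 0.35, OK = 0.30)
  A <- raterProfile("A", rbind(c(.80, .15, .05), c(.15, .70, .15), c(.05, .15, .80)))
  B <- raterProfile("B", rbind(c(.70, .20, .10), c(.20, .60, .20), c(.10, .20, .70)))
  kPop <- populationKappa(A, B, prev)
  reps <- 120
  ks <- vapply(seq_len(reps), function(r) {
    truth <- withr::with_seed(4000 + r,
      sample(ratingLevels(), 100, replace = TRUE, prob = prev[ratingLevels()]))
    tab <- simulateRatings(truth, list(A, B), seed = 8000 + r)
    as.numeric(weightedKappa(raterVector(tab, "A"), raterVector(tab, "B")))
  }, 1)
  se <- stats::sd(ks) / sqrt(reps)
  expect_lt(abs(mean(ks) - kPop), 3 * se + 0.005)
})

test_that("jittered pools are seeded and row-stochastic", {
  base <- matrix(c(.8, .15, .05, .15, .7, .15, .05, .15, .8), 3, byrow = TRUE)
  p1 <- jitterProfiles(base, c("a", "b"), seed = 3)
  p2 <- jitterProfiles(base, c("a", "b"), seed = 3)
  expect_identical(p1[[1]]@confusion, p2[[1]]@confusion)
  expect_false(identical(p1[[1]]@confusion, p1[[2]]@confusion))
  for (p in p1) expect_equal(rowSums(p@confusion), rep(1, 3), ignore_attr = TRUE)
})

test_that("campaigns retire images after the configured number of distinct raters", {
  cfg <- campaignConfig(nImages = 12, retirement = 40, minRatingsPerRater = 0,
                        nRaters = 100, seed = 5)
  pool <- honestPool(100, seed = 6)
  tab <- simulateCampaign(cfg, pool)
  e <- ratingEntries(tab)
  perImage <- table(e$image_id)
  expect_true(all(perImage == 40))
  for (im in imageIds(tab))
    expect_false(anyDuplicated(e$rater_id[e$image_id == im]) > 0)
  # minRatingsPerRater = 0 keeps every contributing rater
  expect_setequal(unique(e$rater_id), raterIds(tab))
})

test_that("low-volume raters are dropped and the per-image counts shrink", {
  cfg <- campaignConfig(nImages = 25, retirement = 30, minRatingsPerRater = 10,
                        nRaters = 80, seed = 9)
  tab <- simulateCampaign(cfg, honestPool(80, seed = 2))
  kept <- table(ratingEntries(tab)$rater_id)
  expect_true(all(kept > 10))
  perImage <- attr(tab, "ratingsPerImage")
  expect_true(all(perImage <= 30))
  expect_lte(mean(perImage), 30)
})

test_that("unreachable retirement is a configuration error", {
  cfg <- campaignConfig(nImages = 5, retirement = 50, nRaters = 10)
  expect_error(simulateCampaign(cfg, honestPool(10)), "unreachable")
})

test_that("bigger honest panels make fewer consensus mistakes", {
  set.seed(2024)
  prev <- c(.35, .35, .30)
  sizes <- c(1, 3, 9, 21)
  reps <- 6
  errs <- matrix(NA_real_, reps, length(sizes))
  pool <- honestPool(21, seed = 4)
  for (r in seq_len(reps)) {
    truth <- withr::with_seed(600 + r,
      sample(ratingLevels(), 120, replace = TRUE, prob = prev))
    names(truth) <- sprintf("i%03d", seq_along(truth))
    tab <- simulateRatings(truth, pool, seed = 900 + r)
    for (s in seq_along(sizes)) {
      cons <- panelConsensus(tab, raterIds(tab)[seq_len(sizes[s])])
      errs[r, s] <- mean(as.character(cons[names(truth)]) !=
                           as.character(asRating(truth)))
    }
  }
  avg <- colMeans(errs)
  expect_true(all(diff(avg) <= 1e-9))
  expect_lt(avg[length(sizes)], avg[1])
})
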