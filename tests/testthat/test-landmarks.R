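test_that("sphere shell spans the expected radial band", {
  s <- makeSphereVolume(radius = 20, n = 56)
  shell <- buildOutlineShell(s$vol, dilateMm = 4, erodeMm = 4)
  expect_s4_class(shell, "LandmarkMask")
  expect_identical(provenance(shell), "computed_shell")
  expect_true(gridCompatible(shell, s$vol))
  rs <- s$r[volumeData(shell) != 0]
  # dilate(20, 4) \ erode(20, 4): radii in (16, 24], thickness 8 mm +- 1 voxel
  expect_gt(min(rs), 16 - 1)
  expect_lte(max(rs), 24 + 1e-9)
  expect_equal(max(rs) - min(rs), 8, tolerance = 1 / 8)
})

test_that("degenerate shells are empty", {
  empty <- BrainVolume(array(0, c(16, 16, 16)))
  expect_equal(sum(volumeData(buildOutlineShell(empty, 4, 4))), 0)
  s <- makeSphereVolume(10, 32)
  expect_equal(sum(volumeData(buildOutlineShell(s$vol, 0, 0))), 0)
})

test_that("shell stays inside the dilation and outside the erosion", {
  m <- makeBlobMask(7)
  shell <- buildOutlineShell(m, 3, 2)
  dil <- dilateMask(m, 3); ero <- erodeMask(m, 2)
  sh <- volumeData(shell)
  expect_true(all(volumeData(dil)[sh != 0] == 1))
  expect_true(all(volumeData(ero)[sh != 0] == 0))
})

test_that("growing either radius never removes shell voxels", {
  for (seed in c(2, 5, 11)) {
    m <- makeBlobMask(seed)
    base <- volumeData(buildOutlineShell(m, 2, 2))
    moreDil <- volumeData(buildOutlineShell(m, 4, 2))
    moreEro <- volumeData(buildOutlineShell(m, 2, 4))
    expect_true(all(moreDil[base != 0] == 1))
    expect_true(all(moreEro[base != 0] == 1))
  }
})

test_that("distance-transform morphology equals ball-structuring-element oracle", {
  for (seed in c(3, 9)) {
    m <- makeBlobMask(seed, n = 20L)
    for (r in c(1.5, 3)) {
      expect_equal(volumeData(dilateMask(m, r)),
                   bruteDilate(volumeData(m), r), label = sprintf("dilate r=%g", r))
      expect_equal(volumeData(erodeMask(m, r)),
                   bruteErode(volumeData(m), r), label = sprintf("erode r=%g", r))
    }
  }
  # anisotropic voxels: radii are millimetres, not voxel counts
  m <- makeBlobMask(13, n = 16L, voxel = c(1, 2, 3))
  expect_equal(volumeData(dilateMask(m, 3.5)),
               bruteDilate(volumeData(m), 3.5, voxel = c(1, 2, 3)))
  expect_equal(volumeData(erodeMask(m, 2.5)),
               bruteErode(volumeData(m), 2.5, voxel = c(1, 2, 3)))
})

test_that("non-binary masks are rejected by morphology", {
  bad <- BrainVolume(array(2, c(16, 16, 16)))
  expect_error(dilateMask(bad, 2), "not binary")
  expect_error(buildOutlineShell(bad, 4, 4), "not binary")
})

test_that("mask merging is a voxelwise union", {
  s <- makeSphereVolume(10, 32)
  shell <- buildOutlineShell(s$vol, 2, 2)
  expect_identical(mergeLandmarkMasks(shell, list()), shell)

  mk <- function(arr) new("LandmarkMask",
                          BrainVolume(arr, affineMatrix(s$vol)),
                          provenance = "user_supplied")
  a1 <- array(0, c(32, 32, 32)); a1[1:4, 1:4, 1:4] <- 1
  a2 <- array(0, c(32, 32, 32)); a2[20:25, 20:25, 20:25] <- 1
  disjoint <- mergeLandmarkMasks(mk(a1), list(mk(a2)))
  expect_identical(provenance(disjoint), "merged")
  expect_equal(sum(volumeData(disjoint)), sum(a1) + sum(a2))

  ov <- volumeData(mergeLandmarkMasks(shell, list(mk(a1))))
  expect_equal(ov, array(as.numeric(volumeData(shell) | a1), dim(a1)))

  off <- mk(a1); off@affine[1, 4] <- off@affine[1, 4] + 1
  expect_error(mergeLandmarkMasks(shell, list(off)), "grid-compatible")
})

test_that("landmark validation reports problems without failing", {
  s <- makeSphereVolume(10, 32)
  shell <- buildOutlineShell(s$vol, 2, 2)
  ok <- validateLandmarkMask(shell, s$vol)
  expect_true(ok$ok)
  expect_equal(ok$voxelCount, sum(volumeData(shell)))

  bad <- shell; bad@data[1, 1, 1] <- 2
  r <- validateLandmarkMask(bad, s$vol)
  expect_false(r$ok)
  expect_true("non-binary" %in% r$reasons)

  shifted <- shell; shifted@affine[2, 4] <- shifted@affine[2, 4] + 3
  r2 <- validateLandmarkMask(shifted, s$vol)
  expect_false(r2$ok)
  expect_true("grid mismatch" %in% r2$reasons)
})
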