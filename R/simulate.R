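# Synthetic phantoms, raters and rating campaigns. These stand in for the
# real template/individual volumes and for human raters, so that the whole
# QC pipeline is exercisable and testable without access to imaging data or
# collected ratings.

# smooth random field as a small sum of cosine modes; deterministic given
# the current RNG state, smooth on the scale of `minWavelengthMm`
cosineField <- function(X, Y, Z, nModes = 6L, minWavelengthMm = 40) {
  f <- 0
  for (m in seq_len(nModes)) {
    k <- stats::runif(3, -1, 1) * (2 * pi / minWavelengthMm)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::rnorm(1)
    f <- f + amp * cos(k[1] * X + k[2] * Y + k[3] * Z + ph)
  }
  f / sqrt(nModes)
}

#' Generate a brain-like phantom volume and its mask
#'
#' Deterministic-for-seed synthetic "template": a smooth ellipsoidal head
#' with internal intensity structure (a bright shell, darker central
#' ventricle-like cavities, and a seeded smooth random texture) and the
#' matching binary brain mask. The affine centres the phantom at the world
#' origin, so the protocol's slice coordinates — scaled to the phantom with
#' [sliceProtocol()]`(scale)` — fall inside the field of view.
#'
#' @param seed integer seed.
#' @param shape grid dimensions (default `c(64, 76, 64)`; all `>= 16`).
#' @param voxelMm isotropic voxel size in mm (default 2).
#' @return List with elements `template` ([BrainVolume-class]) and `mask`
#'   (binary `BrainVolume`).
#' @examples
#' ph <- generatePhantom(seed = 1, shape = c(24, 24, 24), voxelMm = 2)
#' ph$template
#' @export
generatePhantom <- function(seed, shape = c(64, 76, 64), voxelMm = 2) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("'shape' must be three extents of at least 16 voxels", call. = FALSE)
  if (!is.finite(voxelMm) || voxelMm <= 0)
    stop("'voxelMm' must be positive", call. = FALSE)
  affine <- diag(c(rep(voxelMm, 3), 1))
  affine[1:3, 4] <- -(shape - 1) / 2 * voxelMm
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - 1) - (shape[a] - 1) / 2) * voxelMm)
  X <- array(rep(ax[[1]], times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(ax[[3]], each = shape[1] * shape[2]), shape)
  semi <- (shape - 1) / 2 * voxelMm * 0.82
  r2 <- (X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2
  mask <- r2 <= 1
  withSeed(seed, {
    texture <- cosineField(X, Y, Z)
    vshift <- stats::runif(3, -4, 4)  # ventricle position jitter
  })
  rv2 <- ((X - vshift[1]) / (0.28 * semi[1]))^2 +
         ((Y - vshift[2]) / (0.35 * semi[2]))^2 +
         ((Z - vshift[3]) / (0.22 * semi[3]))^2
  intens <- (0.55 + 0.45 * (1 - r2)) * 100 +
    12 * texture +
    40 * exp(-pmax(r2 - 0.55, 0) * 12) -      # bright sub-cortical band
    55 * exp(-rv2 * 3)                         # dark central cavity
  dat <- ifelse(mask, pmax(intens, 0), 0)
  list(template = BrainVolume(dat, affine, space = "phantom"),
       mask = BrainVolume(array(as.numeric(mask), shape), affine,
                          space = "phantom"))
}

# trilinear sample of a 3-D array at fractional 1-based voxel coordinates
# (vectors i, j, k of equal length); outside the grid -> 0
trilinear <- function(vol, i, j, k) {
  dm <- dim(vol)
  i0 <- floor(i); j0 <- floor(j); k0 <- floor(k)
  fi <- i - i0; fj <- j - j0; fk <- k - k0
  out <- numeric(length(i))
  get <- function(ii, jj, kk) {
    ok <- ii >= 1 & ii <= dm[1] & jj >= 1 & jj <= dm[2] & kk >= 1 & kk <= dm[3]
    v <- numeric(length(ii))
    idx <- cbind(ii[ok], jj[ok], kk[ok])
    v[ok] <- vol[idx]
    v
  }
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fi else 1 - fi) * (if (dj) fj else 1 - fj) *
         (if (dk) fk else 1 - fk)
    out <- out + w * get(i0 + di, j0 + dj, k0 + dk)
  }
  out
}

#' Apply a bounded smooth misregistration to a volume
#'
#' Simulates an imperfectly registered individual: the volume is resampled
#' through a smooth random displacement field whose maximum magnitude is
#' exactly `maxDisplacementMm` (0 returns the input unchanged). The
#' displacement is smooth on the ~40 mm scale, mimicking the low-frequency
#' residuals of a failed linear/nonlinear registration rather than voxel
#' noise.
#'
#' @param template a [BrainVolume-class].
#' @param maxDisplacementMm maximum displacement magnitude in mm (`>= 0`).
#' @param seed integer seed.
#' @return A `BrainVolume` on the same grid.
#' @export
perturbRegistration <- function(template, maxDisplacementMm, seed) {
  stopifnot(is(template, "BrainVolume"),
            is.finite(maxDisplacementMm), maxDisplacementMm >= 0)
  if (maxDisplacementMm == 0) return(template)
  dm <- dim(template@data)
  vs <- voxelSize(template)
  ax <- lapply(1:3, function(a) ((seq_len(dm[a]) - 1) - (dm[a] - 1) / 2) * vs[a])
  X <- array(rep(ax[[1]], times = dm[2] * dm[3]), dm)
  Y <- array(rep(rep(ax[[2]], each = dm[1]), times = dm[3]), dm)
  Z <- array(rep(ax[[3]], each = dm[1] * dm[2]), dm)
  d <- withSeed(seed, list(cosineField(X, Y, Z, 4L),
                           cosineField(X, Y, Z, 4L),
                           cosineField(X, Y, Z, 4L)))
  nrm <- sqrt(d[[1]]^2 + d[[2]]^2 + d[[3]]^2)
  mx <- max(nrm)
  if (mx > 0) d <- lapply(d, function(f) f / mx * maxDisplacementMm)
  ii <- as.vector(slice.index(template@data, 1)) + as.vector(d[[1]]) / vs[1]
  jj <- as.vector(slice.index(template@data, 2)) + as.vector(d[[2]]) / vs[2]
  kk <- as.vector(slice.index(template@data, 3)) + as.vector(d[[3]]) / vs[3]
  out <- array(trilinear(template@data, ii, jj, kk), dm)
  BrainVolume(out, template@affine, template@space)
}

#' Construct a simulated rater profile
#'
#' @param raterId character id.
#' @param confusion 3x3 row-stochastic matrix (rows = true class, columns =
#'   reported class, ordered `Fail, Maybe, OK`).
#' @return A [RaterProfile-class].
#' @export
raterProfile <- function(raterId, confusion) {
  dimnames(confusion) <- list(ratingLevels(), ratingLevels())
  new("RaterProfile", raterId = as.character(raterId), confusion = confusion)
}

setMethod("show", "RaterProfile", function(object) {
  cat(sprintf("RaterProfile %s (diag %.2f %.2f %.2f)\n", object@raterId,
              object@confusion[1, 1], object@confusion[2, 2],
              object@confusion[3, 3]))
  invisible(object)
})

#' Draw a heterogeneous pool of raters around a base confusion matrix
#'
#' Each rater's confusion rows are Dirichlet draws centred on the base
#' rows; `concentration` controls how tightly the pool clusters around the
#' base behaviour (higher = more homogeneous). This mimics the
#' expert-versus-crowd quality spread without committing to a behavioural
#' model of volunteers.
#'
#' @param base 3x3 row-stochastic base confusion matrix.
#' @param ids character vector of rater ids to create.
#' @param concentration Dirichlet concentration (default 50).
#' @param seed integer seed.
#' @return List of [RaterProfile-class] objects.
#' @export
jitterProfiles <- function(base, ids, concentration = 50, seed = 1L) {
  stopifnot(all(abs(rowSums(base) - 1) < 1e-9), concentration > 0)
  withSeed(seed, lapply(ids, function(id) {
    cm <- t(apply(base, 1, function(row) {
      g <- stats::rgamma(length(row), shape = pmax(concentration * row, 1e-3))
      g / sum(g)
    }))
    raterProfile(id, cm)
  }))
}

normalizeTruth <- function(truth) {
  if (is.numeric(truth)) truth <- ratingLevels()[truth + 1L]
  t <- asRating(truth)
  if (length(t) == 0L) stop("'truth' must be non-empty", call. = FALSE)
  if (is.null(names(t)))
    names(t) <- sprintf("img%03d", seq_along(t))
  t
}

#' Simulate every rater rating every image
#'
#' Each rater rates each image independently by sampling the confusion row
#' of the image's true class. Deterministic for a given seed.
#'
#' @param truth vector of true classes (`Fail`/`Maybe`/`OK`, or ordinal
#'   codes 0/1/2), optionally named by image id.
#' @param raters list of [RaterProfile-class] objects.
#' @param seed integer seed.
#' @return A [RatingTable-class] with one rating per (image, rater).
#' @export
simulateRatings <- function(truth, raters, seed = 1L) {
  truth <- normalizeTruth(truth)
  stopifnot(length(raters) >= 1L)
  tcode <- as.integer(truth)  # 1..3 in Fail < Maybe < OK order
  withSeed(seed, {
    recs <- lapply(raters, function(rp) {
      stopifnot(is(rp, "RaterProfile"))
      rep_ <- vapply(tcode, function(tc)
        sample.int(3L, 1L, prob = rp@confusion[tc, ]), 1L)
      data.frame(image_id = names(truth), rater_id = rp@raterId,
                 rating = ratingLevels()[rep_], stringsAsFactors = FALSE)
    })
    e <- do.call(rbind, recs)
    RatingTable(e$image_id, e$rater_id, e$rating,
                imageIds = names(truth),
                raterIds = vapply(raters, function(r) r@raterId, ""))
  })
}

#' Closed-form population kappa of two rater profiles
#'
#' The weighted kappa that two confusion-matrix raters would attain on
#' infinitely many images with the given class prevalences: the joint
#' distribution of reported pairs is `J = t(A) diag(prev) B`, from which
#' kappa follows directly. Serves as the analytic reference for simulation
#' calibration.
#'
#' @param profileA,profileB [RaterProfile-class] objects (or bare 3x3
#'   confusion matrices).
#' @param prevalences probability vector of true classes
#'   (`Fail, Maybe, OK`).
#' @param weights kappa weighting scheme (default linear).
#' @return Scalar population kappa.
#' @export
populationKappa <- function(profileA, profileB, prevalences,
                            weights = c("linear", "quadratic", "unweighted")) {
  A <- if (is(profileA, "RaterProfile")) profileA@confusion else profileA
  B <- if (is(profileB, "RaterProfile")) profileB@confusion else profileB
  stopifnot(abs(sum(prevalences) - 1) < 1e-9)
  J <- t(A) %*% (B * prevalences)
  w <- kappaWeights(match.arg(weights), nrow(J))
  po <- sum(w * J)
  pe <- as.numeric(rowSums(J) %*% w %*% colSums(J))
  (po - pe) / (1 - pe)
}

#' Configure a simulated crowdsourced campaign
#'
#' Defaults mirror the protocol's validation conditions: 100 images with
#' true-class mix 35% Fail / 35% Maybe / 30% OK, image retirement after 40
#' ratings, and retention only of raters contributing more than 15 ratings.
#'
#' @param nImages number of images (default 100).
#' @param prevalences true-class probabilities `(Fail, Maybe, OK)`.
#' @param retirement ratings collected per image before retirement
#'   (default 40).
#' @param minRatingsPerRater retention threshold: raters with at most this
#'   many ratings are dropped (default 15).
#' @param nRaters size of the rater pool (default 100).
#' @param seed integer seed.
#' @return A validated list of class `"CampaignConfig"`.
#' @export
campaignConfig <- function(nImages = 100L,
                           prevalences = c(Fail = 0.35, Maybe = 0.35, OK = 0.30),
                           retirement = 40L, minRatingsPerRater = 15L,
                           nRaters = 100L, seed = 1L) {
  stopifnot(nImages >= 1, retirement >= 1, nRaters >= 1,
            minRatingsPerRater >= 0, abs(sum(prevalences) - 1) < 1e-9,
            all(prevalences >= 0))
  structure(list(nImages = as.integer(nImages), prevalences = prevalences,
                 retirement = as.integer(retirement),
                 minRatingsPerRater = as.integer(minRatingsPerRater),
                 nRaters = as.integer(nRaters), seed = as.integer(seed)),
            class = "CampaignConfig")
}

#' Simulate a crowdsourced rating campaign with retirement
#'
#' Every image accrues ratings from `retirement` distinct raters drawn
#' uniformly from the pool (the platform's scheduler is not modelled
#' further); raters contributing no more than `minRatingsPerRater` ratings
#' are then dropped, as in the protocol's data cleaning. The returned
#' table keeps only retained raters; the post-filter ratings-per-image
#' distribution is attached as attribute `"ratingsPerImage"`.
#'
#' @param config a [campaignConfig()] list.
#' @param raterPool list of [RaterProfile-class]; must hold at least
#'   `retirement` raters, otherwise retirement is unreachable.
#' @param truth optional true classes (length `nImages`); generated from
#'   `prevalences` under the config seed when omitted.
#' @return A [RatingTable-class]; attribute `"truth"` carries the true
#'   classes, `"ratingsPerImage"` the post-filter counts.
#' @export
simulateCampaign <- function(config, raterPool, truth = NULL) {
  stopifnot(inherits(config, "CampaignConfig"))
  npool <- length(raterPool)
  if (npool < config$retirement)
    stop(sprintf("retirement of %d unreachable with a pool of %d distinct raters",
                 config$retirement, npool), call. = FALSE)
  ids <- vapply(raterPool, function(r) r@raterId, "")
  withSeed(config$seed, {
    if (is.null(truth)) {
      truth <- sample(ratingLevels(), config$nImages, replace = TRUE,
                      prob = config$prevalences[ratingLevels()])
      names(truth) <- sprintf("img%03d", seq_len(config$nImages))
    }
    truth <- normalizeTruth(truth)
    tcode <- as.integer(truth)
    recs <- vector("list", length(truth))
    for (i in seq_along(truth)) {
      who <- sample.int(npool, config$retirement)
      rep_ <- vapply(who, function(w)
        sample.int(3L, 1L, prob = raterPool[[w]]@confusion[tcode[i], ]), 1L)
      recs[[i]] <- data.frame(image_id = names(truth)[i], rater_id = ids[who],
                              rating = ratingLevels()[rep_],
                              stringsAsFactors = FALSE)
    }
  })
  e <- do.call(rbind, recs)
  cnt <- table(e$rater_id)
  kept <- names(cnt)[cnt > config$minRatingsPerRater]
  e <- e[e$rater_id %in% kept, ]
  tab <- RatingTable(e$image_id, e$rater_id, e$rating,
                     imageIds = names(truth), raterIds = ids[ids %in% kept])
  attr(tab, "truth") <- truth
  attr(tab, "ratingsPerImage") <- table(factor(e$image_id, levels = names(truth)))
  tab
}
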