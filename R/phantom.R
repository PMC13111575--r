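# run expr under a fixed RNG seed without disturbing the caller's RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

.NOISE_KINDS <- c("gaussian", "speckle", "salt_pepper", "quantum", "impulse")

#' Phantom configuration
#'
#' Defines a seeded synthetic mammogram-like image: a smooth textured
#' background (low-pass-filtered noise), an optional elliptical lesion whose
#' pixels are the ground-truth mask, bright artifact spots standing in for
#' view labels and markers, and one of five radiographic noise models.
#'
#' @param side image side in pixels (default 256; use 1024 for full-size
#'   demos).
#' @param backgroundSmoothness Gaussian blur sigma, in pixels, applied to
#'   the background noise field (default 8).
#' @param lesion list: `present`, `center` (0-based row/col, `NULL` for the
#'   image center), `axes` (semi-axes in pixels, `NULL` for side/10 and
#'   side/14), `intensityBoost` (levels added inside the ellipse).
#' @param artifactSpots list: `count`, `sizeRange` (min/max side in pixels),
#'   `intensity` (level of the spots, near the top of the range).
#' @param noise list: `kind` (one of gaussian, speckle, salt_pepper,
#'   quantum, impulse, or `NULL` for a clean phantom) and `params` for
#'   [injectNoise()].
#' @param levels gray-level count R (default 256).
#' @param seed RNG seed; the phantom is fully deterministic given the seed.
#' @return a validated config list of class `PhantomConfig`.
#' @export
phantomConfig <- function(side = 256, backgroundSmoothness = 8,
                          lesion = list(present = FALSE),
                          artifactSpots = list(count = 2,
                                               sizeRange = c(16, 32),
                                               intensity = 245),
                          noise = list(kind = NULL, params = list()),
                          levels = 256, seed = 1) {
  cfg <- list(side = as.integer(side),
              backgroundSmoothness = backgroundSmoothness,
              lesion = utils::modifyList(
                list(present = FALSE, center = NULL, axes = NULL,
                     intensityBoost = 60), lesion),
              artifactSpots = utils::modifyList(
                list(count = 2, sizeRange = c(16, 32), intensity = 245),
                artifactSpots),
              noise = utils::modifyList(list(kind = NULL, params = list()),
                                        noise),
              levels = levels, seed = seed)
  if (cfg$side < 32) stop("phantom side must be at least 32 pixels")
  if (!is.null(cfg$noise$kind) && !cfg$noise$kind %in% .NOISE_KINDS)
    stop("unknown noise kind '", cfg$noise$kind, "'; valid kinds: ",
         paste(.NOISE_KINDS, collapse = ", "))
  if (cfg$lesion$present) {
    ctr <- cfg$lesion$center
    ax <- cfg$lesion$axes
    if (is.null(ctr)) ctr <- c(cfg$side / 2, cfg$side / 2)
    if (is.null(ax)) ax <- c(cfg$side / 10, cfg$side / 14)
    if (ctr[1] - ax[1] < 0 || ctr[1] + ax[1] > cfg$side - 1 ||
        ctr[2] - ax[2] < 0 || ctr[2] + ax[2] > cfg$side - 1)
      stop("lesion geometry falls outside image bounds")
    cfg$lesion$center <- ctr
    cfg$lesion$axes <- ax
  }
  if (cfg$artifactSpots$count > 0 &&
      max(cfg$artifactSpots$sizeRange) > cfg$side)
    stop("artifact spot size range too large for the image side")
  class(cfg) <- "PhantomConfig"
  cfg
}

#' Generate a synthetic phantom case
#'
#' Deterministic given the config seed: two calls with the same config give
#' bit-identical images and masks. The clean image (before noise) is
#' returned alongside the noisy one so denoising efficacy can be measured
#' against ground truth.
#'
#' @param config a [phantomConfig()].
#' @return a list of class `PhantomCase`: `image` (the [GrayImage] with
#'   noise applied, if configured), `clean` (the noise-free [GrayImage]),
#'   `mask` (the lesion [BinaryMask]), `spots` (data frame of planted
#'   artifact geometry), `config`.
#' @examples
#' pc <- generatePhantomCase(phantomConfig(side = 64, seed = 7))
#' dim(pc$image)
#' @export
generatePhantomCase <- function(config) {
  stopifnot(inherits(config, "PhantomConfig"))
  .withSeed(config$seed, {
    side <- config$side
    R <- config$levels
    # textured low-frequency background
    z <- matrix(stats::rnorm(side^2), side, side)
    # the Gaussian brush (2 ceil(3 sigma) + 1 wide) must fit inside the image
    sig <- min(config$backgroundSmoothness, (side %/% 2 - 1) / 3)
    z <- EBImage::imageData(EBImage::gblur(EBImage::Image(z), sigma = sig))
    z <- (z - min(z)) / (max(z) - min(z))        # [0, 1]
    bg <- 0.15 * (R - 1) + z * 0.40 * (R - 1)    # mid-range breast-like field
    mask <- matrix(0L, side, side)
    if (config$lesion$present) {
      ctr <- config$lesion$center
      ax <- config$lesion$axes
      yy <- matrix(0:(side - 1), side, side)
      xx <- t(yy)
      inside <- ((yy - ctr[1]) / ax[1])^2 + ((xx - ctr[2]) / ax[2])^2 <= 1
      bg[inside] <- bg[inside] + config$lesion$intensityBoost
      mask[inside] <- 1L
    }
    spots <- NULL
    ns <- config$artifactSpots$count
    if (ns > 0) {
      sz <- config$artifactSpots$sizeRange
      rows <- list()
      for (k in seq_len(ns)) {
        he <- sample(sz[1]:sz[2], 1)
        wi <- sample(sz[1]:sz[2], 1)
        r0 <- sample(0:(side - he), 1)
        c0 <- sample(0:(side - wi), 1)
        bg[(r0 + 1):(r0 + he), (c0 + 1):(c0 + wi)] <- config$artifactSpots$intensity
        rows[[k]] <- data.frame(row0 = r0, col0 = c0, he = he, wi = wi)
      }
      spots <- do.call(rbind, rows)
    }
    clean <- GrayImage(pmin(pmax(floor(bg + 0.5), 0), R - 1), levels = R)
    noisy <- clean
    if (!is.null(config$noise$kind))
      noisy <- injectNoise(clean, config$noise$kind, config$noise$params,
                           seed = config$seed + 1)
    structure(list(image = noisy, clean = clean, mask = BinaryMask(mask),
                   spots = spots, config = config),
              class = "PhantomCase")
  })
}

#' Inject radiographic noise into an image
#'
#' The five supported models: `gaussian` (additive, `sigma` as a fraction of
#' R), `speckle` (multiplicative Gaussian, `sigma`), `salt_pepper` (`rate`
#' of corrupted pixels, split 50/50 between level R-1 and level 0),
#' `quantum` (Poisson photon noise at `photons` mean counts for a full-scale
#' pixel), and `impulse` (`rate` of pixels replaced by uniform random
#' levels). Output is rounded and clipped to `[0, R-1]`; a zero rate/sigma
#' is an exact no-op.
#'
#' @param img a [GrayImage].
#' @param kind one of `"gaussian"`, `"speckle"`, `"salt_pepper"`,
#'   `"quantum"`, `"impulse"`.
#' @param params list of model parameters (defaults: sigma 0.05, speckle
#'   sigma 0.2, rate 0.05, photons 100).
#' @param seed RNG seed.
#' @return a [GrayImage] of the same shape and level count.
#' @export
injectNoise <- function(img, kind, params = list(), seed = 1) {
  stopifnot(is(img, "GrayImage"))
  if (!kind %in% .NOISE_KINDS)
    stop("unknown noise kind '", kind, "'; valid kinds: ",
         paste(.NOISE_KINDS, collapse = ", "))
  px <- pixels(img)
  R <- nLevels(img)
  n <- length(px)
  out <- .withSeed(seed, switch(kind,
    gaussian = {
      sigma <- params$sigma %||% 0.05
      if (sigma == 0) px else px + stats::rnorm(n, 0, sigma * R)
    },
    speckle = {
      sigma <- params$sigma %||% 0.2
      if (sigma == 0) px else px * (1 + stats::rnorm(n, 0, sigma))
    },
    salt_pepper = {
      rate <- params$rate %||% 0.05
      if (rate == 0) px else {
        hit <- stats::runif(n) < rate
        salt <- stats::runif(n) < 0.5
        v <- px
        v[hit & salt] <- R - 1
        v[hit & !salt] <- 0
        v
      }
    },
    quantum = {
      photons <- params$photons %||% 100
      lam <- px / (R - 1) * photons
      stats::rpois(n, lam) / photons * (R - 1)
    },
    impulse = {
      rate <- params$rate %||% 0.05
      if (rate == 0) px else {
        hit <- stats::runif(n) < rate
        v <- px
        v[hit] <- floor(stats::runif(sum(hit)) * R)
        v
      }
    }
  ))
  out <- matrix(pmin(pmax(floor(out + 0.5), 0), R - 1), nrow(px), ncol(px))
  GrayImage(out, levels = R)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.PERTURB_SCENARIOS <- c("gaussian_low", "gaussian_medium",
                        "contrast_reduction", "downsample")

#' Apply a robustness perturbation scenario
#'
#' Scenarios mirror common acquisition degradations: additive Gaussian noise
#' at sigma = 0.05 R (`gaussian_low`) or 0.10 R (`gaussian_medium`), a 15%
#' contrast reduction (deviations from the image mean scaled by 0.85 and
#' rounded), and resolution degradation (2x2 block-mean downsampling
#' followed by nearest-neighbor upsampling to the original size).
#'
#' @param img a [GrayImage].
#' @param scenario one of `"gaussian_low"`, `"gaussian_medium"`,
#'   `"contrast_reduction"`, `"downsample"`.
#' @param seed RNG seed for the stochastic scenarios.
#' @return a perturbed [GrayImage] of the same shape.
#' @export
perturbImage <- function(img, scenario, seed = 1) {
  stopifnot(is(img, "GrayImage"))
  if (!scenario %in% .PERTURB_SCENARIOS)
    stop("unknown scenario '", scenario, "'; valid scenarios: ",
         paste(.PERTURB_SCENARIOS, collapse = ", "))
  px <- pixels(img)
  R <- nLevels(img)
  switch(scenario,
    gaussian_low = injectNoise(img, "gaussian", list(sigma = 0.05), seed),
    gaussian_medium = injectNoise(img, "gaussian", list(sigma = 0.10), seed),
    contrast_reduction = {
      m <- mean(px)
      out <- pmin(pmax(floor(m + 0.85 * (px - m) + 0.5), 0), R - 1)
      GrayImage(out, levels = R)
    },
    downsample = {
      nr <- nrow(px); nc <- ncol(px)
      ri <- ceiling(seq_len(nr) / 2)
      ci <- ceiling(seq_len(nc) / 2)
      sums <- rowsum(t(rowsum(px, ri)), ci)                 # block sums
      cnt <- rowsum(t(rowsum(matrix(1, nr, nc), ri)), ci)   # block sizes
      blocks <- t(sums / cnt)
      out <- blocks[ri, ci, drop = FALSE]                   # nearest upsample
      dimnames(out) <- NULL
      GrayImage(pmin(pmax(floor(out + 0.5), 0), R - 1), levels = R)
    }
  )
}

#' Generate a synthetic cohort of phantom cases
#'
#' Exactly `round(nCases * benignFraction)` cases are benign; the rest are
#' malignant and carry a lesion with a ground-truth mask. Each case has the
#' configured views, all sharing the case label; per-view seeds are derived
#' from the cohort seed so the cohort is fully reproducible.
#'
#' @param nCases number of cases (>= 1).
#' @param benignFraction fraction of benign cases, in (0, 1); default 0.60,
#'   the standard screening-benchmark class mix.
#' @param views view names per case (default CC and MLO).
#' @param lateralities lateralities per case (default "L").
#' @param baseConfig a [phantomConfig()] used as the template for every
#'   image.
#' @param seed cohort seed.
#' @param materialize when `TRUE`, actually generate the images; when
#'   `FALSE` (default) only the manifest records and per-image seeds are
#'   produced, which is what splitting and auditing need.
#' @return a list of class `PhantomCohort`: `manifest` (data.frame with
#'   case_id, laterality, view, label, seed) and `cases` (named list of
#'   `PhantomCase`, empty unless materialized).
#' @export
generateCohort <- function(nCases, benignFraction = 0.60,
                           views = c("CC", "MLO"), lateralities = "L",
                           baseConfig = phantomConfig(), seed = 1,
                           materialize = FALSE) {
  stopifnot(nCases >= 1, benignFraction > 0, benignFraction < 1)
  nBenign <- round(nCases * benignFraction)
  labels <- .withSeed(seed, sample(rep(c("benign", "malignant"),
                                       c(nBenign, nCases - nBenign))))
  grid <- expand.grid(view = views, laterality = lateralities,
                      case = seq_len(nCases), stringsAsFactors = FALSE)
  manifest <- data.frame(
    case_id = sprintf("case%05d", grid$case),
    laterality = grid$laterality,
    view = grid$view,
    label = labels[grid$case],
    seed = (seed + 7919 * grid$case +
            104729 * as.integer(factor(paste(grid$view, grid$laterality)))) %%
           2147483647,
    stringsAsFactors = FALSE
  )
  manifest <- manifest[order(manifest$case_id, manifest$laterality,
                             manifest$view), ]
  rownames(manifest) <- NULL
  cases <- list()
  if (materialize) {
    for (r in seq_len(nrow(manifest))) {
      cfg <- unclass(baseConfig)
      cfg$seed <- manifest$seed[r]
      cfg$lesion$present <- manifest$label[r] == "malignant"
      cfg <- do.call(phantomConfig, cfg)
      key <- paste(manifest$case_id[r], manifest$laterality[r],
                   manifest$view[r], sep = "_")
      cases[[key]] <- generatePhantomCase(cfg)
    }
  }
  structure(list(manifest = manifest, cases = cases), class = "PhantomCohort")
}

#' Write a materialized cohort to disk
#'
#' Writes each view's image and mask as PNGs plus a `manifest.csv` with
#' image/mask paths, ready for [runPipeline()] or external tools.
#'
#' @param cohort a materialized `PhantomCohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "PhantomCohort"))
  if (length(cohort$cases) == 0)
    stop("cohort has no materialized images; regenerate with materialize = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mf <- cohort$manifest
  mf$image_path <- NA_character_
  mf$mask_path <- NA_character_
  for (r in seq_len(nrow(mf))) {
    key <- paste(mf$case_id[r], mf$laterality[r], mf$view[r], sep = "_")
    pc <- cohort$cases[[key]]
    ip <- file.path(dir, paste0(key, ".png"))
    mp <- file.path(dir, paste0(key, "_mask.png"))
    writeGrayImage(pc$image, ip)
    writeMask(pc$mask, mp)
    mf$image_path[r] <- ip
    mf$mask_path[r] <- mp
  }
  out <- file.path(dir, "manifest.csv")
  writeManifest(mf[setdiff(names(mf), "seed")], out)
  invisible(out)
}
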