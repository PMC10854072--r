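# Data handling: reading and standardizing real images/volumes, the
# flip/rotation augmentation, and the seeded synthetic generator emulating
# five biomedical imaging challenges. A sample is a plain list with
# elements `image` (array spatial x channels, values in [0,1]) and `mask`
# (binary array, spatial only); synthetic samples additionally carry the
# generating object geometry in `objects`, making the ground truth exactly
# re-derivable.

#' Create a synthetic dataset configuration
#'
#' Presets emulate the qualitative difficulty of five imaging modalities:
#' \describe{
#'   \item{fluorescence}{bright high-contrast nuclei on a dark background
#'     with visible debris objects that are excluded from the mask, and
#'     per-nucleus brightness variation ("easy" preset: sharp boundaries).}
#'   \item{endoscopy}{polyps with low contrast to a textured mucosa-like
#'     background and strongly blurred boundaries (the "hard" preset).}
#'   \item{dermoscopy}{a single darker lesion on a textured skin-like
#'     background; both foreground and background are textured.}
#'   \item{electron}{dense tissue filling most of the frame, so the
#'     foreground is the majority class (over-segmentation pressure).}
#'   \item{mri3d}{3D volumes with four channels sharing one lesion
#'     geometry; the lesion is strongly elevated only in the designated
#'     contrast channel (channel 4).}
#' }
#' All randomness derives from `seed`: the same configuration and seed
#' reproduce the dataset bitwise. Masks are computed from the pre-blur
#' object geometry, so the ground truth is exact regardless of blur,
#' texture or noise.
#'
#' @param preset preset name (see above).
#' @param nImages number of samples.
#' @param size per-axis spatial extents (one value recycled, or a full
#'   vector); minimum 16 per axis.
#' @param objectsPerImage integer range (min, max); `NULL` = preset default.
#' @param contrast foreground-background intensity gap; `NULL` = preset.
#' @param boundaryBlurSigma image blur in pixels; `NULL` = preset.
#' @param noiseSd additive Gaussian noise; `NULL` = preset.
#' @param debrisCount distractor objects (fluorescence); `NULL` = preset.
#' @param channels image channels; `NULL` = preset default (1 for
#'   fluorescence/electron, 3 for endoscopy/dermoscopy, 4 for mri3d).
#' @param seed integer seed.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(preset, nImages = 10, size = 64,
                            objectsPerImage = NULL, contrast = NULL,
                            boundaryBlurSigma = NULL, noiseSd = NULL,
                            debrisCount = NULL, channels = NULL, seed = 1) {
  def <- switch(preset,
    fluorescence = list(objects = c(4L, 9L), contrast = 0.65, blur = 0.6,
                        noise = 0.03, debris = 6L, channels = 1L),
    endoscopy = list(objects = c(1L, 2L), contrast = 0.12, blur = 2.5,
                     noise = 0.03, debris = 0L, channels = 3L),
    dermoscopy = list(objects = c(1L, 1L), contrast = 0.25, blur = 1.5,
                      noise = 0.02, debris = 0L, channels = 3L),
    electron = list(objects = c(6L, 12L), contrast = 0.2, blur = 0.8,
                    noise = 0.05, debris = 0L, channels = 1L),
    mri3d = list(objects = c(1L, 3L), contrast = 0.45, blur = 1.0,
                 noise = 0.04, debris = 0L, channels = 4L),
    stopf("unknown preset '%s'", preset))
  rank <- if (preset == "mri3d") 3L else 2L
  size <- as.integer(size)
  if (length(size) == 1) size <- rep(size, rank)
  if (length(size) != rank)
    stopf("size must have %d extents for preset '%s'", rank, preset)
  new("SyntheticConfig", preset = preset, nImages = as.integer(nImages),
      size = size,
      objectsPerImage = if (is.null(objectsPerImage)) def$objects
                        else as.integer(objectsPerImage),
      contrast = if (is.null(contrast)) def$contrast else contrast,
      boundaryBlurSigma = if (is.null(boundaryBlurSigma)) def$blur
                          else boundaryBlurSigma,
      noiseSd = if (is.null(noiseSd)) def$noise else noiseSd,
      debrisCount = if (is.null(debrisCount)) def$debris
                    else as.integer(debrisCount),
      channels = if (is.null(channels)) def$channels else as.integer(channels),
      seed = as.integer(seed))
}

# ------------------------------------------------------ blob geometry ----

# One object = a cluster of 1..lobes random ellipses/ellipsoids. All
# parameters are stored so the mask can be re-derived exactly.
randomObject <- function(size, rmin, rmax, lobes = 2L) {
  rank <- length(size)
  ctr <- vapply(seq_len(rank), function(a)
    stats::runif(1, rmax + 1, size[a] - rmax - 1), numeric(1))
  nl <- sample.int(lobes, 1)
  parts <- lapply(seq_len(nl), function(i) {
    off <- if (i == 1) rep(0, rank) else stats::runif(rank, -rmin, rmin)
    list(center = ctr + off,
         radii = stats::runif(rank, rmin, rmax),
         angle = stats::runif(1, 0, pi))
  })
  list(parts = parts)
}

# exact binary mask of a list of objects on an integer pixel grid
#' Render the exact mask of stored object geometry
#'
#' Recomputes the binary mask of a synthetic sample from its stored object
#' parameters (ellipse/ellipsoid unions on the pixel grid). Generated
#' samples satisfy `identical(renderMask(objects, size), mask)`.
#'
#' @param objects the `objects` element of a synthetic sample.
#' @param size spatial extents.
#' @return binary array of dimension `size`.
#' @export
renderMask <- function(objects, size) {
  rank <- length(size)
  m <- array(0, size)
  grid <- lapply(size, function(n) seq_len(n) - 0.5)
  for (obj in objects) {
    for (p in obj$parts) {
      if (rank == 2) {
        ca <- cos(p$angle); sa <- sin(p$angle)
        dx <- outer(grid[[1]] - p$center[1], rep(1, size[2]))
        dy <- outer(rep(1, size[1]), grid[[2]] - p$center[2])
        u <- (ca * dx + sa * dy) / p$radii[1]
        v <- (-sa * dx + ca * dy) / p$radii[2]
        m[u * u + v * v <= 1] <- 1
      } else {
        # axis-aligned ellipsoids with an xy-plane rotation
        ca <- cos(p$angle); sa <- sin(p$angle)
        for (z in seq_len(size[3])) {
          dz <- (grid[[3]][z] - p$center[3]) / p$radii[3]
          if (abs(dz) > 1) next
          dx <- outer(grid[[1]] - p$center[1], rep(1, size[2]))
          dy <- outer(rep(1, size[1]), grid[[2]] - p$center[2])
          u <- (ca * dx + sa * dy) / p$radii[1]
          v <- (-sa * dx + ca * dy) / p$radii[2]
          sl <- m[, , z]
          sl[u * u + v * v <= 1 - dz * dz] <- 1
          m[, , z] <- sl
        }
      }
    }
  }
  m
}

smoothNoiseField <- function(size, sigma, amplitude) {
  f <- array(stats::rnorm(prod(size)), size)
  f <- gauss_blur(f, as.integer(size), length(size), sigma)
  dim(f) <- size
  rng <- max(abs(f))
  if (rng > 0) f <- f / rng
  f * amplitude
}

# ----------------------------------------------------------- 2D images ----

#' Generate a synthetic 2D segmentation dataset
#'
#' @param config a [SyntheticConfig-class] with a 2D preset.
#' @return list of samples; each a list with `image`
#'   `(H x W x channels)`, binary `mask` `(H x W)`, and the generating
#'   `objects`.
#' @examples
#' d <- generateSynthetic2d(syntheticConfig("fluorescence", nImages = 2,
#'                                          size = 32, seed = 7))
#' @export
generateSynthetic2d <- function(config) {
  validObject(config)
  if (config@preset == "mri3d")
    stopf("use generateSynthetic3d for the mri3d preset")
  size <- config@size
  preset <- config@preset
  withSeed(config@seed, {
    lapply(seq_len(config@nImages), function(i) {
      n_obj <- sample(seq(config@objectsPerImage[1],
                          config@objectsPerImage[2]), 1)
      rmax <- switch(preset,
                     fluorescence = max(4, round(min(size) / 9)),
                     endoscopy = max(6, round(min(size) / 5)),
                     dermoscopy = max(8, round(min(size) / 4)),
                     electron = max(6, round(min(size) / 4)))
      rmin <- max(2, round(rmax / 2.5))
      lobes <- if (preset %in% c("endoscopy", "dermoscopy")) 3L else 1L
      objects <- lapply(seq_len(n_obj), function(o)
        randomObject(size, rmin, rmax, lobes))
      mask <- renderMask(objects, size)

      bgLevel <- switch(preset, fluorescence = 0.08, endoscopy = 0.45,
                        dermoscopy = 0.55, electron = 0.35)
      fgSign <- if (preset == "dermoscopy") -1 else 1
      textureAmp <- switch(preset, fluorescence = 0.02, endoscopy = 0.1,
                           dermoscopy = 0.15, electron = 0.08)
      base <- bgLevel + smoothNoiseField(size, max(2, min(size) / 16),
                                         textureAmp)
      # per-object intensity jitter (inconsistent brightness)
      img <- base
      for (obj in objects) {
        om <- renderMask(list(obj), size)
        jit <- stats::runif(1, -0.15, 0.15) * config@contrast
        img[om == 1] <- bgLevel + fgSign * (config@contrast + jit)
      }
      # debris: rendered in the image, excluded from the mask
      if (config@debrisCount > 0) {
        for (d in seq_len(config@debrisCount)) {
          dob <- randomObject(size, 1, max(2, round(rmin / 2)), 1L)
          dm <- renderMask(list(dob), size)
          img[dm == 1 & mask == 0] <- bgLevel + 0.45 * config@contrast
        }
      }
      img <- gauss_blur(img, as.integer(size), 2L,
                        config@boundaryBlurSigma)
      dim(img) <- size
      ch <- config@channels
      arr <- array(0, c(size, ch))
      chOff <- if (ch > 1) seq(-0.03, 0.03, length.out = ch) else 0
      for (c in seq_len(ch))
        arr[, , c] <- img + chOff[c] +
          stats::rnorm(prod(size), 0, config@noiseSd)
      arr[arr < 0] <- 0
      arr[arr > 1] <- 1
      list(image = arr, mask = mask, objects = objects)
    })
  })
}

# ----------------------------------------------------------- 3D volumes ----

#' Generate a synthetic multi-channel 3D dataset
#'
#' Four channels share one lesion geometry; channel-specific contrasts put
#' most of the lesion signal in the designated contrast channel (4).
#'
#' @param config a [SyntheticConfig-class] with `preset = "mri3d"`.
#' @return list of samples with `image` `(X x Y x Z x 4)`, binary `mask`
#'   `(X x Y x Z)`, and `objects`.
#' @export
generateSynthetic3d <- function(config) {
  validObject(config)
  if (config@preset != "mri3d")
    stopf("generateSynthetic3d requires the mri3d preset")
  size <- config@size
  withSeed(config@seed, {
    lapply(seq_len(config@nImages), function(i) {
      n_obj <- sample(seq(config@objectsPerImage[1],
                          config@objectsPerImage[2]), 1)
      rmax <- max(4, round(min(size) / 6))
      rmin <- max(3, round(rmax / 2))
      objects <- lapply(seq_len(n_obj), function(o)
        randomObject(size, rmin, rmax, 2L))
      mask <- renderMask(objects, size)
      chContrast <- config@contrast * c(0.25, 0.35, 0.5, 1.0)
      arr <- array(0, c(size, config@channels))
      for (c in seq_len(config@channels)) {
        bg <- 0.25 + 0.05 * c
        vol <- bg + smoothNoiseField(size, max(2, min(size) / 16), 0.05)
        vol[mask == 1] <- bg + chContrast[c]
        vol <- gauss_blur(vol, as.integer(size), 3L,
                          config@boundaryBlurSigma)
        vol <- vol + stats::rnorm(prod(size), 0, config@noiseSd)
        arr[, , , c] <- vol
      }
      arr[arr < 0] <- 0
      arr[arr > 1] <- 1
      list(image = arr, mask = mask, objects = objects)
    })
  })
}

# --------------------------------------------------------- augmentation ----

flipArray <- function(x, axis) {
  idx <- lapply(dim(x), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# right-angle rotation in the first two axes; 90/270 require square extents
rotArray <- function(x, degrees) {
  if (degrees %% 360 == 0) return(x)
  d <- dim(x)
  if (degrees %% 180 != 0 && d[1] != d[2])
    stopf("90/270 degree rotations require square extents")
  perm <- seq_along(d)
  if (degrees %% 180 != 0) {
    perm[1:2] <- c(2L, 1L)
    x <- aperm(x, perm)
  }
  switch(as.character(degrees %% 360),
         "90" = flipArray(x, 1L),
         "180" = flipArray(flipArray(x, 1L), 2L),
         "270" = flipArray(x, 2L))
}

applyTransform <- function(arr, tr) {
  if (tr$rot != 0) arr <- rotArray(arr, tr$rot)
  if (tr$hflip) arr <- flipArray(arr, 2L)
  if (tr$vflip) arr <- flipArray(arr, 1L)
  arr
}

#' Augment a dataset by seeded flips and rotations
#'
#' Returns the original samples followed by `(factor - 1) * n` augmented
#' copies; each copy applies one randomly drawn flip/right-angle-rotation
#' combination identically to image and mask. With the default
#' `factor = 3` the training set is exactly tripled.
#'
#' @param samples list of samples.
#' @param config an [AugmentConfig-class].
#' @return list of `factor * length(samples)` samples. Augmented samples
#'   carry the applied transform in their `transform` element.
#' @export
augmentDataset <- function(samples, config = new("AugmentConfig")) {
  validObject(config)
  if (config@factor == 1L) return(samples)
  sz <- dim(samples[[1]]$mask)
  rots <- config@rotations
  if (sz[1] != sz[2]) rots <- rots[rots %% 180 == 0]
  out <- samples
  withSeed(config@seed, {
    for (rep_ in seq_len(config@factor - 1L)) {
      for (i in seq_along(samples)) {
        repeat {
          tr <- list(
            hflip = config@hflip && stats::runif(1) < 0.5,
            vflip = config@vflip && stats::runif(1) < 0.5,
            rot = if (length(rots) && stats::runif(1) < 0.75)
              sample(rots, 1) else 0L)
          if (tr$hflip || tr$vflip || tr$rot != 0) break
        }
        s <- samples[[i]]
        out[[length(out) + 1L]] <- list(
          image = applyTransform(s$image, tr),
          mask = applyTransform(s$mask, tr),
          transform = tr)
      }
    }
  })
  out
}

# ------------------------------------------------------------------- IO ----

#' Write a dataset to disk with a manifest
#'
#' 2D samples are written as PNG image/mask pairs, 3D samples as NIfTI
#' volume/label pairs, plus a `manifest.csv` with columns
#' `image, mask, split`.
#'
#' @param samples list of samples.
#' @param dir output directory (created if needed).
#' @param split split label written to the manifest (recycled).
#' @return path of the manifest CSV, invisibly.
#' @export
writeDataset <- function(samples, dir, split = "train") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rank <- length(dim(samples[[1]]$mask))
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    if (rank == 2) {
      ip <- file.path(dir, sprintf("img_%04d.png", i))
      mp <- file.path(dir, sprintf("mask_%04d.png", i))
      EBImage::writeImage(s$image, ip)
      EBImage::writeImage(s$mask, mp)
    } else {
      ip <- file.path(dir, sprintf("vol_%04d.nii.gz", i))
      mp <- file.path(dir, sprintf("lab_%04d.nii.gz", i))
      RNifti::writeNifti(s$image, ip)
      RNifti::writeNifti(s$mask, mp)
    }
    data.frame(image = ip, mask = mp, split = rep(split, length.out =
      length(samples))[i], stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

readOne <- function(path, rank) {
  if (!file.exists(path)) stopf("cannot read '%s': file does not exist", path)
  if (rank == 2) {
    img <- tryCatch(EBImage::readImage(path), error = function(e)
      stopf("cannot read image '%s': %s", path, conditionMessage(e)))
    a <- EBImage::imageData(img)
    if (max(a) > 1) a <- a / 255   # raw 8-bit counts
    a
  } else {
    v <- tryCatch(RNifti::readNifti(path), error = function(e)
      stopf("cannot read volume '%s': %s", path, conditionMessage(e)))
    as.array(v)
  }
}

#' Read and standardize a dataset
#'
#' Reads the image/mask pairs of a manifest, standardizes intensities to
#' \[0, 1\] (2D images are divided by 255 when given as 8-bit counts; 3D
#' volumes are min-max scaled per volume), resamples to `targetSize`
#' (linear interpolation for images; masks are re-binarized at 0.5 after
#' interpolation), and returns in-memory samples.
#'
#' @param manifest data.frame with columns `image` and `mask`, or the path
#'   of a manifest CSV written by [writeDataset()].
#' @param rank spatial rank of the stored data (2 or 3).
#' @param targetSize per-axis output extents, or `NULL` to keep native
#'   sizes.
#' @return list of samples (`image`, `mask`).
#' @export
loadAndStandardize <- function(manifest, rank = 2, targetSize = NULL) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("image", "mask") %in% names(manifest)))
    stopf("manifest must have 'image' and 'mask' columns")
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- readOne(manifest$image[i], rank)
    msk <- readOne(manifest$mask[i], rank)
    if (length(dim(img)) == rank) dim(img) <- c(dim(img), 1L)
    if (length(dim(msk)) == rank + 1L) {   # collapse mask channel
      msk <- msk[slice.index(msk, rank + 1L) == 1]
      dim(msk) <- dim(img)[seq_len(rank)]
    }
    if (rank == 3) {   # per-volume min-max standardization
      lo <- min(img); hi <- max(img)
      img <- if (hi > lo) (img - lo) / (hi - lo) else img * 0
    }
    if (!identical(as.integer(dim(msk)), as.integer(dim(img)[seq_len(rank)])))
      stopf("image/mask extent mismatch for '%s'", manifest$image[i])
    if (!is.null(targetSize)) {
      if (length(targetSize) != rank)
        stopf("targetSize must have %d extents", rank)
      di <- dim(img)
      img <- resize_linear(img, as.integer(di), as.integer(targetSize), rank)
      dim(img) <- c(as.integer(targetSize), di[rank + 1L])
      dm <- dim(msk)
      msk <- resize_linear(msk, as.integer(dm), as.integer(targetSize), rank)
      dim(msk) <- as.integer(targetSize)
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    msk <- (msk >= 0.5) + 0
    list(image = img, mask = msk)
  })
}
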