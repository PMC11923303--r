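# Seeded synthetic H&E patch/slide generator. Nuclei are rendered through a
# Beer-Lambert stain model: lymphocytes as small hematoxylin-dense disks,
# tumor nuclei as larger boundary-perturbed ellipses with an eosin cytoplasm
# halo, over an optional low-amplitude eosin stroma field.

#' Specification of one synthetic patch
#'
#' @param nLymphocytes,nTumorCells non-negative cell counts to render.
#' @param lymphRadiusPx,tumorRadiusPx length-2 radius ranges in pixels.
#'   The lymphocyte maximum must stay below the tumor minimum so the two
#'   classes are separable by area.
#' @param stainProfile rendering stain basis ([StainProfile-class]).
#' @param noiseSd Gaussian intensity noise (0-255 scale) added after
#'   rendering (default 0).
#' @param background `"stroma"` (low-amplitude eosin field, default) or
#'   `"white"`.
#' @param lymphHConc,tumorHConc,tumorEConc concentration ranges: hematoxylin
#'   in lymphocyte and tumor nuclei, and eosin in the tumor cytoplasm halo.
#'   Nuclei displace the stroma field so near-pure pixels of each stain
#'   exist for stain estimation.
#' @param stromaEConc base and amplitude of the stroma eosin field.
#' @param perturbAmp radial perturbation amplitude of tumor nucleus
#'   boundaries (fraction of radius, default 0.25).
#' @param size patch edge length in pixels (default 150).
#' @param seed integer seed; rendering is bit-deterministic given the spec.
#' @return A named list (class `PatchSpec`).
#' @export
patchSpec <- function(nLymphocytes = 0, nTumorCells = 0,
                      lymphRadiusPx = c(5, 7), tumorRadiusPx = c(12, 20),
                      stainProfile = defaultStainProfile(), noiseSd = 0,
                      background = c("stroma", "white"),
                      lymphHConc = c(0.8, 1.2), tumorHConc = c(0.4, 0.8),
                      tumorEConc = c(0.5, 0.9), stromaEConc = c(0.12, 0.12),
                      perturbAmp = 0.25, size = 150, seed = 1) {
  background <- match.arg(background)
  stopifnot(nLymphocytes >= 0, nTumorCells >= 0,
            length(lymphRadiusPx) == 2, length(tumorRadiusPx) == 2,
            all(lymphRadiusPx > 0), all(tumorRadiusPx > 0),
            noiseSd >= 0, size >= 16)
  if (max(lymphRadiusPx) >= min(tumorRadiusPx))
    stop("lymphocyte radius range must lie strictly below the tumor range")
  structure(list(nLymphocytes = as.integer(nLymphocytes),
                 nTumorCells = as.integer(nTumorCells),
                 lymphRadiusPx = lymphRadiusPx, tumorRadiusPx = tumorRadiusPx,
                 stainProfile = stainProfile, noiseSd = noiseSd,
                 background = background, lymphHConc = lymphHConc,
                 tumorHConc = tumorHConc, tumorEConc = tumorEConc,
                 stromaEConc = stromaEConc, perturbAmp = perturbAmp,
                 size = as.integer(size), seed = as.integer(seed)),
            class = "PatchSpec")
}

# Smooth periodic radial perturbation profile (low-order Fourier), amplitude
# `amp` as a fraction of the base radius.
radialProfile <- function(k = 360, amp = 0.25) {
  a <- rnorm(3)
  b <- rnorm(3)
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  f <- rowSums(vapply(1:3, function(m) a[m] * cos(m * th) + b[m] * sin(m * th),
                      numeric(k)))
  1 + f / max(abs(f), 1e-9) * amp
}

#' Generate one synthetic H&E patch
#'
#' Places the requested nuclei by rejection sampling with a non-overlap
#' guarantee, renders hematoxylin/eosin concentration fields through the
#' Beer-Lambert model (`I = io * exp(-S c) - 1`, quantized to 0-255), and
#' labels the patch by [ruleLabel()] applied to the true counts.
#'
#' @param spec a [patchSpec()].
#' @return List with `pixels` (size x size x 3 array), `cells` (data.frame of
#'   rendered cells: centroidRow, centroidCol, area, circularity, meanHConc,
#'   cellClass), and `label` (0 = TIL-positive, 1 = TIL-negative,
#'   2 = other/necrotic). Throws `PatchTIL_capacityError` when the requested
#'   cells cannot be placed without overlap.
#' @examples
#' p <- generatePatch(patchSpec(nLymphocytes = 3, nTumorCells = 1, seed = 7))
#' p$label          # 0: TIL-positive
#' nrow(p$cells)    # 4 rendered nuclei
#' @export
generatePatch <- function(spec) {
  stopifnot(inherits(spec, "PatchSpec"))
  withSeed(spec$seed, {
    size <- spec$size
    hconc <- matrix(0, size, size)
    econc <- matrix(0, size, size)
    if (spec$background == "stroma") {
      base <- matrix(rnorm(225), 15, 15)
      f <- as.matrix(EBImage::resize(EBImage::Image(base), w = size, h = size))
      rng <- range(f)
      f <- if (diff(rng) > 0) (f - rng[1]) / diff(rng) else f * 0
      econc <- spec$stromaEConc[1] + spec$stromaEConc[2] * f
    }
    rr <- row(hconc)
    cc <- col(hconc)
    placed <- list()
    place <- function(spacingRad, margin) {
      for (i in seq_len(2000)) {
        cy <- runif(1, margin + 1, size - margin)
        cx <- runif(1, margin + 1, size - margin)
        ok <- TRUE
        for (p in placed)
          if (sqrt((p[1] - cy)^2 + (p[2] - cx)^2) <= p[3] + spacingRad + 3) {
            ok <- FALSE
            break
          }
        if (ok) return(c(cy, cx))
      }
      ptStop("PatchTIL_capacityError",
             "cannot place %d lymphocytes + %d tumor cells in a %dx%d patch without overlap",
             spec$nLymphocytes, spec$nTumorCells, size, size)
    }
    cells <- list()
    addCell <- function(mask, cls, hc) {
      cells[[length(cells) + 1L]] <<- data.frame(
        centroidRow = mean(rr[mask]), centroidCol = mean(cc[mask]),
        area = sum(mask), circularity = maskCircularity(mask),
        meanHConc = hc, cellClass = cls)
    }
    for (i in seq_len(spec$nTumorCells)) {
      r0 <- runif(1, spec$tumorRadiusPx[1], spec$tumorRadiusPx[2])
      asp <- runif(1, 0.7, 1)
      ang0 <- runif(1, 0, pi)
      prof <- radialProfile(360, spec$perturbAmp)
      rNuc <- r0 * max(prof)
      ctr <- place(rNuc, rNuc * 1.4 + 1)
      placed[[length(placed) + 1L]] <- c(ctr, rNuc)
      dy <- rr - ctr[1]
      dx <- cc - ctr[2]
      u <- dy * cos(ang0) + dx * sin(ang0)
      v <- -dy * sin(ang0) + dx * cos(ang0)
      dEff <- sqrt(u^2 + (v / asp)^2)
      th <- atan2(v, u)
      idx <- pmin(pmax(1L, as.integer(round((th + pi) / (2 * pi) * 359)) + 1L),
                  360L)
      rb <- r0 * prof[idx]
      inside <- dEff <= rb
      halo <- dEff > rb & dEff <= rb * 1.4
      hc <- runif(1, spec$tumorHConc[1], spec$tumorHConc[2])
      ec <- runif(1, spec$tumorEConc[1], spec$tumorEConc[2])
      hconc[inside] <- hc
      econc[inside] <- 0                # nucleus displaces the stroma field
      econc[halo] <- econc[halo] + ec
      addCell(inside, "tumor", hc)
    }
    for (i in seq_len(spec$nLymphocytes)) {
      rad <- runif(1, spec$lymphRadiusPx[1], spec$lymphRadiusPx[2])
      ctr <- place(rad, rad + 1)
      placed[[length(placed) + 1L]] <- c(ctr, rad)
      inside <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2) <= rad
      hc <- runif(1, spec$lymphHConc[1], spec$lymphHConc[2])
      hconc[inside] <- hc
      econc[inside] <- 0
      addCell(inside, "lymphocyte", hc)
    }
    S <- stainMatrix(spec$stainProfile)
    io <- backgroundIntensity(spec$stainProfile)
    od <- array(0, c(size, size, 3))
    for (ch in 1:3) od[, , ch] <- hconc * S[ch, 1] + econc * S[ch, 2]
    pixels <- odToRGB(od, io)
    if (spec$noiseSd > 0)
      pixels <- clip255(round(pixels + rnorm(length(pixels), 0, spec$noiseSd)))
    cellsDf <- if (length(cells)) do.call(rbind, cells) else
      data.frame(centroidRow = numeric(), centroidCol = numeric(),
                 area = numeric(), circularity = numeric(),
                 meanHConc = numeric(), cellClass = character())
    list(pixels = pixels, cells = cellsDf,
         label = ruleLabel(spec$nLymphocytes, spec$nTumorCells),
         hConcTrue = hconc, eConcTrue = econc)
  })
}

# Circularity 4*pi*A/P^2 of a binary mask, perimeter measured along the
# 8-connected object contour.
maskCircularity <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  oc <- EBImage::ocontour(lab)
  if (!length(oc)) return(NA_real_)
  p <- oc[[1]]
  p <- rbind(p, p[1, , drop = FALSE])
  per <- sum(sqrt(rowSums(diff(p)^2)))
  if (per <= 0) return(1)
  min(4 * pi * sum(mask) / per^2, 1.1)
}

#' Specification of one synthetic slide
#'
#' A slide is a `gridRows x gridCols` mosaic of 150-px patches. A seeded
#' subset of cells (`tissueFraction` of them) carries tissue; the rest are
#' rendered white (blank). Each tissue patch draws a class from
#' `labelProbs` and then cell counts from per-class ranges, so the realized
#' ground-truth label composition is programmable.
#'
#' @param gridRows,gridCols grid dimensions (>= 1).
#' @param tissueFraction fraction of patches carrying tissue, in \[0, 1\].
#' @param labelProbs length-3 probabilities of drawing a TIL-positive /
#'   TIL-negative / other tissue patch (default proportional to 1:1.5:1.5).
#' @param posLymph,posTumor,negLymph,negTumor,otherLymph inclusive count
#'   ranges sampled per class (TIL-positive needs at least 3 lymphocytes
#'   and 1 tumor cell; TIL-negative fewer than 3 lymphocytes and at least
#'   1 tumor cell; other has 0 tumor cells).
#' @param noiseSd,stainProfile,patchSize forwarded to every [patchSpec()].
#' @param seed master seed; patch `(i, j)` of the row-major grid uses the
#'   derived seed `(seed * 1009 + i * gridCols + j) mod (2^31 - 2) + 1`.
#' @return A named list (class `SlideSpec`).
#' @export
slideSpec <- function(gridRows, gridCols, tissueFraction = 1,
                      labelProbs = c(1, 1.5, 1.5) / 4,
                      posLymph = c(3, 8), posTumor = c(1, 3),
                      negLymph = c(0, 2), negTumor = c(1, 3),
                      otherLymph = c(0, 5), noiseSd = 0,
                      stainProfile = defaultStainProfile(),
                      patchSize = 150, seed = 1) {
  stopifnot(gridRows >= 1, gridCols >= 1,
            tissueFraction >= 0, tissueFraction <= 1,
            length(labelProbs) == 3, all(labelProbs >= 0),
            sum(labelProbs) > 0)
  structure(list(gridRows = as.integer(gridRows),
                 gridCols = as.integer(gridCols),
                 tissueFraction = tissueFraction,
                 labelProbs = labelProbs / sum(labelProbs),
                 posLymph = posLymph, posTumor = posTumor,
                 negLymph = negLymph, negTumor = negTumor,
                 otherLymph = otherLymph, noiseSd = noiseSd,
                 stainProfile = stainProfile,
                 patchSize = as.integer(patchSize), seed = as.integer(seed)),
            class = "SlideSpec")
}

sampleRange <- function(rng) {
  if (rng[1] == rng[2]) as.integer(rng[1]) else
    sample(seq.int(rng[1], rng[2]), 1)
}

#' Generate a synthetic slide with ground truth
#'
#' Assembles a `(patchSize * gridRows) x (patchSize * gridCols)` RGB raster.
#' Non-tissue patches render near-white and pass the blank filter; tissue
#' patches render via [generatePatch()] with per-patch derived seeds.
#'
#' @param spec a [slideSpec()].
#' @param slideId identifier stored in the manifest (default "synthetic").
#' @return List with `pixels` (the slide raster) and `manifest`
#'   (a [TileManifest-class] whose data carries `isBlank`, ground-truth
#'   `label`, `nLymph`, `nTumor`, `seed` per patch).
#' @export
generateSlide <- function(spec, slideId = "synthetic") {
  stopifnot(inherits(spec, "SlideSpec"))
  ps <- spec$patchSize
  n <- spec$gridRows * spec$gridCols
  nTissue <- round(spec$tissueFraction * n)
  tissueIdx <- withSeed(spec$seed, sample.int(n, nTissue))
  tissue <- logical(n)
  tissue[tissueIdx] <- TRUE
  H <- ps * spec$gridRows
  W <- ps * spec$gridCols
  slide <- array(239, c(H, W, 3))   # io - 1: the unstained background level
  rows <- vector("list", n)
  for (k in seq_len(n) - 1L) {
    i <- k %/% spec$gridCols
    j <- k %% spec$gridCols
    sd <- childSeed(spec$seed, k)
    if (tissue[k + 1L]) {
      cls <- withSeed(sd + 7L, sample.int(3, 1, prob = spec$labelProbs)) - 1L
      counts <- withSeed(sd + 13L, switch(as.character(cls),
        "0" = c(sampleRange(spec$posLymph), sampleRange(spec$posTumor)),
        "1" = c(sampleRange(spec$negLymph), sampleRange(spec$negTumor)),
        "2" = c(sampleRange(spec$otherLymph), 0L)))
      p <- generatePatch(patchSpec(
        nLymphocytes = counts[1], nTumorCells = counts[2],
        stainProfile = spec$stainProfile, noiseSd = spec$noiseSd,
        background = "stroma", size = ps, seed = sd))
      slide[i * ps + seq_len(ps), j * ps + seq_len(ps), ] <- p$pixels
      rows[[k + 1L]] <- data.frame(gridRow = i, gridCol = j, isBlank = FALSE,
                                   label = p$label, nLymph = counts[1],
                                   nTumor = counts[2], seed = sd)
    } else {
      if (spec$noiseSd > 0) {
        blk <- withSeed(sd, clip255(round(
          239 + rnorm(ps * ps * 3, 0, min(spec$noiseSd, 5)))))
        slide[i * ps + seq_len(ps), j * ps + seq_len(ps), ] <-
          array(blk, c(ps, ps, 3))
      }
      rows[[k + 1L]] <- data.frame(gridRow = i, gridCol = j, isBlank = TRUE,
                                   label = NA_integer_, nLymph = NA_integer_,
                                   nTumor = NA_integer_, seed = sd)
    }
  }
  manifest <- TileManifest(slideId, c(H, W), ps, do.call(rbind, rows))
  list(pixels = slide, manifest = manifest)
}

#' Generate a labeled synthetic patch dataset
#'
#' Draws `nTotal` patches whose ground-truth labels follow `labelRatio`
#' (largest-remainder rounding; ties to the lowest class code), each rendered
#' independently with a derived seed.
#'
#' @param nTotal total number of patches (>= 3).
#' @param labelRatio length-3 positive ratio of TIL-positive : TIL-negative :
#'   other patches (default `c(1, 1.5, 1.5)`).
#' @param noiseSd,stainProfile forwarded to [patchSpec()].
#' @param posLymph,posTumor,negLymph,negTumor,otherLymph per-class count
#'   ranges as in [slideSpec()].
#' @param seed master seed; patch `k` (0-based) uses derived seed
#'   `(seed * 1009 + k) mod (2^31 - 2) + 1`.
#' @return List with `patches` (list of pixel arrays), `labels` (integer
#'   vector), and `manifest` (data.frame: index, label, nLymph, nTumor, seed).
#' @export
generateLabeledDataset <- function(nTotal, labelRatio = c(1, 1.5, 1.5),
                                   noiseSd = 0,
                                   stainProfile = defaultStainProfile(),
                                   posLymph = c(3, 8), posTumor = c(1, 3),
                                   negLymph = c(0, 2), negTumor = c(1, 3),
                                   otherLymph = c(0, 5), seed = 1) {
  if (nTotal < 3) stop("nTotal must be >= 3 (one patch per class)")
  stopifnot(length(labelRatio) == 3, all(labelRatio > 0))
  counts <- ratioCounts(nTotal, labelRatio)
  labels <- rep.int(0:2, counts)
  patches <- vector("list", nTotal)
  manifest <- vector("list", nTotal)
  for (k in seq_len(nTotal) - 1L) {
    sd <- childSeed(seed, k)
    cls <- labels[k + 1L]
    cnt <- withSeed(sd + 13L, switch(as.character(cls),
      "0" = c(sampleRange(posLymph), sampleRange(posTumor)),
      "1" = c(sampleRange(negLymph), sampleRange(negTumor)),
      "2" = c(sampleRange(otherLymph), 0L)))
    p <- generatePatch(patchSpec(nLymphocytes = cnt[1], nTumorCells = cnt[2],
                                 stainProfile = stainProfile,
                                 noiseSd = noiseSd, seed = sd))
    patches[[k + 1L]] <- p$pixels
    manifest[[k + 1L]] <- data.frame(index = k, label = cls,
                                     nLymph = cnt[1], nTumor = cnt[2],
                                     seed = sd)
  }
  list(patches = patches, labels = labels,
       manifest = do.call(rbind, manifest))
}

# Apportion n into 3 classes by ratio, largest-remainder method, ties broken
# toward the lowest class code.
ratioCounts <- function(n, ratio) {
  w <- ratio / sum(ratio)
  base <- floor(n * w)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * w - base
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Write a generated dataset to disk
#'
#' Patches as PNG files plus a `labels.tsv` manifest, the on-disk layout the
#' CLI consumes.
#'
#' @param dataset result of [generateLabeledDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(dataset$patches)) {
    png::writePNG(dataset$patches[[k]] / 255,
                  file.path(dir, sprintf("patch_%05d.png", k - 1L)))
  }
  write.table(dataset$manifest, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
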