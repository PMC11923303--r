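# Three-class patch labeling: the labeling rule, a rule-based reference
# backend built on hematoxylin nucleus detection, dataset split utilities,
# and a small trainable neural backend.

LABEL_CODES <- 0:2
LABEL_NAMES <- c("TIL_POSITIVE", "TIL_NEGATIVE", "OTHER_NECROTIC")

#' Patch label codes and names
#'
#' Labels follow the encoding 0 = TIL-positive, 1 = TIL-negative,
#' 2 = other (non-tumor / necrotic).
#'
#' @return `labelCodes()` the integer codes; `labelNames()` a named character
#'   vector mapping code to name.
#' @export
labelCodes <- function() LABEL_CODES

#' @rdname labelCodes
#' @export
labelNames <- function() stats::setNames(LABEL_NAMES, LABEL_CODES)

#' The patch labeling rule
#'
#' A patch is TIL-positive (0) with at least 3 detected lymphocytes and at
#' least 1 detected tumor cell; TIL-negative (1) with at least 1 tumor cell
#' and fewer than 3 lymphocytes; other/necrotic (2) with no tumor cells,
#' regardless of the number of lymphocytes.
#'
#' @param nLymphocytes,nTumorCells non-negative counts (vectorized).
#' @return Integer label code(s) in `0:2`.
#' @examples
#' ruleLabel(3, 1)   # 0
#' ruleLabel(2, 7)   # 1
#' ruleLabel(50, 0)  # 2
#' @export
ruleLabel <- function(nLymphocytes, nTumorCells) {
  if (any(nLymphocytes < 0) || any(nTumorCells < 0))
    stop("cell counts must be non-negative")
  ifelse(nTumorCells == 0L, 2L, ifelse(nLymphocytes >= 3L, 0L, 1L))
}

#' Nucleus-detector parameters
#'
#' Defaults are calibrated to the geometry of the synthetic generator
#' (lymphocyte disks of radius 5-7 px, tumor nuclei of radius 12-20 px).
#'
#' @param hThresholdMode `"fixed"` (default; threshold the smoothed
#'   hematoxylin concentration map at `fixedThreshold`) or `"otsu"` (Otsu
#'   threshold over the map, floored at `minConcentration`). The fixed
#'   default sits between background unmixing crosstalk (< 0.1) and the
#'   faintest rendered nucleus (0.4); Otsu can overshoot faint tumor nuclei
#'   when bright lymphocytes dominate the histogram.
#' @param fixedThreshold hematoxylin concentration threshold for fixed mode.
#' @param minAreaPx components smaller than this are dropped as noise.
#' @param lymphAreaRange inclusive area range (px^2) of a lymphocyte nucleus.
#' @param tumorMinAreaPx minimum area of a tumor nucleus; must exceed
#'   `max(lymphAreaRange)`.
#' @param circularityMin minimum circularity `4*pi*A/P^2` for a lymphocyte.
#' @param smoothingSigma Gaussian smoothing (px) of the concentration map.
#' @param minConcentration absolute floor on the hematoxylin threshold; a
#'   map whose maximum falls below it yields no detections.
#' @return Named list of parameters.
#' @export
detectorParams <- function(hThresholdMode = c("fixed", "otsu"),
                           fixedThreshold = 0.25, minAreaPx = 20,
                           lymphAreaRange = c(40, 280), tumorMinAreaPx = 320,
                           circularityMin = 0.75, smoothingSigma = 1,
                           minConcentration = 0.2) {
  hThresholdMode <- match.arg(hThresholdMode)
  stopifnot(minAreaPx > 0, all(lymphAreaRange > 0),
            lymphAreaRange[1] < lymphAreaRange[2],
            tumorMinAreaPx > lymphAreaRange[2],
            circularityMin > 0, smoothingSigma >= 0)
  list(hThresholdMode = hThresholdMode, fixedThreshold = fixedThreshold,
       minAreaPx = minAreaPx, lymphAreaRange = lymphAreaRange,
       tumorMinAreaPx = tumorMinAreaPx, circularityMin = circularityMin,
       smoothingSigma = smoothingSigma, minConcentration = minConcentration)
}

#' Detect nuclei in an H&E patch
#'
#' Unmixes the hematoxylin concentration with the given stain profile,
#' Gaussian-smooths it, thresholds (Otsu over the map, floored at
#' `minConcentration`, or a fixed threshold), labels 8-connected components,
#' and classifies each surviving component: lymphocyte when its area falls
#' in `lymphAreaRange` and circularity is at least `circularityMin`; tumor
#' when area is at least `tumorMinAreaPx`; otherwise other. Deterministic.
#'
#' @param pixels HxWx3 patch, values 0-255.
#' @param profile [StainProfile-class] used for unmixing (default the
#'   canonical reference).
#' @param params a [detectorParams()] list.
#' @return data.frame of detected cells with columns `centroidRow`,
#'   `centroidCol`, `area`, `circularity`, `meanHConc`, `cellClass`.
#' @export
detectNuclei <- function(pixels, profile = defaultStainProfile(),
                         params = detectorParams()) {
  assertPatch(pixels)
  empty <- data.frame(centroidRow = numeric(), centroidCol = numeric(),
                      area = numeric(), circularity = numeric(),
                      meanHConc = numeric(), cellClass = character())
  conc <- stainConcentrations(pixels, profile)
  ch <- conc$h
  if (params$smoothingSigma > 0)
    ch <- as.matrix(EBImage::gblur(EBImage::Image(ch),
                                   sigma = params$smoothingSigma))
  mx <- max(ch)
  if (mx < params$minConcentration) return(empty)
  thr <- if (params$hThresholdMode == "otsu")
    max(EBImage::otsu(EBImage::Image(ch / mx), range = c(0, 1)) * mx,
        params$minConcentration)
  else params$fixedThreshold
  lab <- EBImage::bwlabel(EBImage::Image(ch > thr))
  labMat <- as.matrix(lab)
  nObj <- max(labMat)
  if (nObj == 0) return(empty)
  areas <- tabulate(labMat[labMat > 0], nbins = nObj)
  keep <- which(areas >= params$minAreaPx)
  if (!length(keep)) return(empty)
  contours <- EBImage::ocontour(lab)
  out <- lapply(keep, function(i) {
    mask <- labMat == i
    p <- contours[[i]]
    p <- rbind(p, p[1, , drop = FALSE])
    per <- sum(sqrt(rowSums(diff(p)^2)))
    circ <- if (per > 0) 4 * pi * areas[i] / per^2 else 1
    data.frame(centroidRow = mean(row(mask)[mask]),
               centroidCol = mean(col(mask)[mask]),
               area = areas[i], circularity = circ,
               meanHConc = mean(conc$h[mask]),
               cellClass = if (areas[i] >= params$tumorMinAreaPx) "tumor"
                 else if (areas[i] >= params$lymphAreaRange[1] &&
                          areas[i] <= params$lymphAreaRange[2] &&
                          circ >= params$circularityMin) "lymphocyte"
                 else "other")
  })
  do.call(rbind, out)
}

#' The rule-based reference classifier backend
#'
#' Detects nuclei and applies [ruleLabel()] to the detected counts;
#' probabilities are the degenerate one-hot vector of the chosen label.
#'
#' @param profile [StainProfile-class] for unmixing.
#' @param params a [detectorParams()] list.
#' @return A backend: a list with a `predict(pixels)` function returning a
#'   `Prediction` (fields `label`, `probabilities`) and a `name`.
#' @export
ruleBackend <- function(profile = defaultStainProfile(),
                        params = detectorParams()) {
  list(name = "rule",
       predict = function(pixels) {
         cells <- detectNuclei(pixels, profile, params)
         lab <- ruleLabel(sum(cells$cellClass == "lymphocyte"),
                          sum(cells$cellClass == "tumor"))
         pr <- c(0, 0, 0)
         pr[lab + 1L] <- 1
         list(label = lab, probabilities = pr)
       })
}

#' Classify one patch with a backend
#'
#' Validates the backend's output against the `Prediction` contract:
#' probabilities on the 3-simplex and `label = argmax` with ties broken
#' toward the lowest class code.
#'
#' @param pixels HxWx3 patch.
#' @param backend a backend (e.g. [ruleBackend()] or [trainPatchNet()]).
#' @return List with `label` (0/1/2) and `probabilities` (length 3,
#'   summing to 1).
#' @export
classifyPatch <- function(pixels, backend) {
  if (!is.list(backend) || !is.function(backend$predict))
    stop("backend must provide a predict() function")
  pred <- backend$predict(pixels)
  pr <- pred$probabilities
  if (length(pr) != 3 || any(pr < -1e-9) || abs(sum(pr) - 1) > 1e-6)
    stop("backend returned probabilities off the 3-simplex")
  lab <- which.max(pr) - 1L    # which.max takes the first (lowest code) tie
  list(label = lab, probabilities = pr)
}

#' Classify every retained patch of a slide
#'
#' Runs the backend over all non-blank patches of a filtered manifest.
#'
#' @param manifest a [TileManifest-class] with up-to-date `isBlank` flags.
#' @param pixels the slide raster.
#' @param backend a classifier backend.
#' @param normalize normalize each patch with [normalizePatch()] before
#'   classification (default FALSE).
#' @param target,macenko target profile and parameters for normalization.
#' @return data.frame: slideId, gridRow, gridCol, label, p0, p1, p2.
#' @export
classifyPatches <- function(manifest, pixels, backend, normalize = FALSE,
                            target = defaultStainProfile(),
                            macenko = macenkoParams()) {
  stopifnot(is(manifest, "TileManifest"))
  d <- manifestData(manifest)
  d <- d[!d$isBlank, , drop = FALSE]
  if (!nrow(d))
    return(data.frame(slideId = character(), gridRow = integer(),
                      gridCol = integer(), label = integer(),
                      p0 = numeric(), p1 = numeric(), p2 = numeric()))
  ps <- patchSize(manifest)
  out <- lapply(seq_len(nrow(d)), function(k) {
    p <- patchAt(pixels, d$gridRow[k], d$gridCol[k], ps)
    if (normalize) p <- normalizePatch(p, target, macenko)
    pred <- classifyPatch(p, backend)
    data.frame(slideId = slideId(manifest), gridRow = d$gridRow[k],
               gridCol = d$gridCol[k], label = pred$label,
               p0 = pred$probabilities[1], p1 = pred$probabilities[2],
               p2 = pred$probabilities[3])
  })
  do.call(rbind, out)
}

#' Stratified dataset split
#'
#' Splits items into train/validation (per-label fraction within one item of
#' `trainFrac`) or into `nFolds` disjoint, exhaustive, label-stratified
#' folds. An optional stratum key stratifies within label x stratum.
#'
#' @param labels integer label per item.
#' @param trainFrac training fraction (default 0.8), used when `nFolds` is
#'   NULL.
#' @param nFolds number of cross-validation folds, or NULL.
#' @param strata optional stratum key per item (e.g. cancer type).
#' @param seed integer seed.
#' @return With `nFolds = NULL`, a logical vector (`TRUE` = train);
#'   otherwise an integer fold assignment in `1:nFolds`.
#' @export
splitDataset <- function(labels, trainFrac = 0.8, nFolds = NULL,
                         strata = NULL, seed = 1) {
  n <- length(labels)
  key <- if (is.null(strata)) as.character(labels) else
    paste(labels, strata, sep = "\r")
  groups <- split(seq_len(n), key)
  withSeed(seed, {
    if (is.null(nFolds)) {
      train <- logical(n)
      for (idx in groups) {
        k <- round(length(idx) * trainFrac)
        train[sample(idx, k)] <- TRUE
      }
      train
    } else {
      if (any(vapply(groups, length, 0L) < nFolds))
        stop("need at least nFolds items per label (and stratum)")
      fold <- integer(n)
      for (idx in groups)
        fold[sample(idx)] <- rep_len(seq_len(nFolds), length(idx))
      fold
    }
  })
}

#' Train a small neural patch classifier
#'
#' An optional trainable backend: each patch is resized to a fixed square
#' network input, summarized by stain-morphology features (a size histogram
#' of thresholded hematoxylin components plus stain means), and fed to a
#' single-hidden-layer softmax network. Training is seeded but, unlike the
#' rule backend, stochastic in nature.
#'
#' @param patches list of HxWx3 pixel arrays.
#' @param labels integer labels (0/1/2); all three classes must be present.
#' @param inputSize network input edge length; patches are resized to it
#'   before feature extraction (default 150, the native patch size).
#' @param hidden hidden units (default 8).
#' @param maxit training iterations (default 500).
#' @param decay weight decay (default 1e-4).
#' @param profile [StainProfile-class] used for stain unmixing.
#' @param seed integer seed.
#' @return A backend honoring the same contract as [ruleBackend()].
#' @export
trainPatchNet <- function(patches, labels, inputSize = 150, hidden = 8,
                          maxit = 500, decay = 1e-4,
                          profile = defaultStainProfile(), seed = 1) {
  if (length(unique(labels)) < 3)
    stop("training data must contain all three classes")
  feat <- t(vapply(patches, patchFeatures, numeric(8),
                   inputSize = inputSize, profile = profile))
  y <- factor(labels, levels = 0:2)
  fit <- withSeed(seed,
    nnet::nnet(feat, nnet::class.ind(y), size = hidden, softmax = TRUE,
               maxit = maxit, decay = decay, trace = FALSE,
               MaxNWts = (ncol(feat) + 1) * hidden + (hidden + 1) * 3 + 1))
  list(name = "net",
       predict = function(pixels) {
         f <- matrix(patchFeatures(pixels, inputSize, profile), nrow = 1)
         pr <- as.numeric(predict(fit, f))
         pr <- pmax(pr, 1e-12)
         pr <- pr / sum(pr)
         list(label = which.max(pr) - 1L, probabilities = pr)
       })
}

# Stain-morphology feature vector: counts of thresholded hematoxylin
# components in five area bins, total nucleus area, mean H and E
# concentration. Patch is resized to the network input size first.
patchFeatures <- function(pixels, inputSize, profile) {
  if (dim(pixels)[1] != inputSize || dim(pixels)[2] != inputSize) {
    img <- EBImage::resize(EBImage::Image(pixels / 255, colormode = "Color"),
                           w = inputSize, h = inputSize)
    pixels <- clip255(round(array(img, c(inputSize, inputSize, 3)) * 255))
  }
  conc <- stainConcentrations(pixels, profile)
  ch <- as.matrix(EBImage::gblur(EBImage::Image(conc$h), sigma = 1))
  lab <- EBImage::bwlabel(EBImage::Image(ch > 0.25))
  lm <- as.matrix(lab)
  nObj <- max(lm)
  areas <- if (nObj > 0) tabulate(lm[lm > 0], nbins = nObj) else numeric()
  areas <- areas[areas >= 20]
  bins <- c(20, 80, 160, 320, 640, Inf)
  cnt <- vapply(1:5, function(b) sum(areas >= bins[b] & areas < bins[b + 1]),
                numeric(1))
  c(cnt, sum(areas), mean(ch), mean(conc$e))
}
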