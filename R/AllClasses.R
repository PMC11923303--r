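#' StainProfile: an H&E optical-density stain basis
#'
#' Holds a 3x2 optical-density stain matrix (column 1 = hematoxylin,
#' column 2 = eosin; rows = R, G, B), the per-stain 99th-percentile
#' concentration scales used for normalization, and the background
#' (unstained) transmitted intensity `io`.
#'
#' @slot stainMatrix 3x2 numeric matrix with unit-norm, non-negative columns.
#' @slot maxConcentration length-2 positive numeric; 99th-percentile
#'   concentration per stain (hematoxylin, eosin).
#' @slot io background intensity on the 0-255 scale (default 240).
#'
#' @aliases StainProfile-class
#' @exportClass StainProfile
setClass("StainProfile",
  representation(stainMatrix = "matrix", maxConcentration = "numeric",
                 io = "numeric"),
  validity = function(object) {
    M <- object@stainMatrix
    if (!all(dim(M) == c(3L, 2L))) return("stainMatrix must be 3x2")
    if (any(M < -1e-8)) return("stainMatrix entries must be non-negative")
    nrm <- sqrt(colSums(M^2))
    if (any(abs(nrm - 1) > 1e-6)) return("stainMatrix columns must be unit-norm")
    if (length(object@maxConcentration) != 2L ||
        any(object@maxConcentration <= 0))
      return("maxConcentration must be 2 positive values")
    if (length(object@io) != 1L || object@io <= 0)
      return("io must be a single positive intensity")
    TRUE
  })

#' Construct a StainProfile
#'
#' @param stainMatrix 3x2 optical-density matrix (hematoxylin, eosin columns);
#'   columns are renormalized to unit length.
#' @param maxConcentration length-2 positive vector of per-stain concentration
#'   scales (99th percentiles).
#' @param io background intensity, 0-255 scale.
#' @return A [StainProfile-class] object.
#' @examples
#' sp <- defaultStainProfile()
#' stainMatrix(sp)
#' @export
StainProfile <- function(stainMatrix, maxConcentration = c(1, 1), io = 240) {
  stainMatrix <- as.matrix(stainMatrix)
  nrm <- sqrt(colSums(stainMatrix^2))
  if (any(nrm <= 0)) stop("stain vectors must be non-zero")
  stainMatrix <- sweep(stainMatrix, 2, nrm, "/")
  new("StainProfile", stainMatrix = stainMatrix,
      maxConcentration = as.numeric(maxConcentration), io = as.numeric(io))
}

#' The canonical H&E reference stain profile
#'
#' The widely used reference hematoxylin/eosin optical-density basis with its
#' standard 99th-percentile concentration scales; the default normalization
#' target and the default rendering basis of the synthetic generator.
#'
#' @param io background intensity (default 240).
#' @return A [StainProfile-class].
#' @export
defaultStainProfile <- function(io = 240) {
  M <- matrix(c(0.5626, 0.7201, 0.4062,
                0.2159, 0.8012, 0.5581), nrow = 3)
  StainProfile(M, maxConcentration = c(1.9705, 1.0308), io = io)
}

#' @describeIn StainProfile accessor for the 3x2 stain matrix.
#' @param object,x a `StainProfile`.
#' @export
stainMatrix <- function(x) {
  stopifnot(is(x, "StainProfile"))
  x@stainMatrix
}

#' @describeIn StainProfile accessor for the per-stain concentration scales.
#' @export
maxConcentration <- function(x) {
  stopifnot(is(x, "StainProfile"))
  x@maxConcentration
}

#' @describeIn StainProfile accessor for the background intensity.
#' @export
backgroundIntensity <- function(x) {
  stopifnot(is(x, "StainProfile"))
  x@io
}

setMethod("show", "StainProfile", function(object) {
  cat("StainProfile (io =", object@io, ")\n")
  M <- round(object@stainMatrix, 4)
  dimnames(M) <- list(c("R", "G", "B"), c("hematoxylin", "eosin"))
  print(M)
  cat("maxConcentration:", round(object@maxConcentration, 4), "\n")
})

#' TileManifest: the tiling grid of one slide
#'
#' Records slide identity and dimensions, the patch size, and one row per
#' grid cell with its blank flag and (when known) ground-truth or predicted
#' label and true cell counts.
#'
#' @slot slideId character scalar.
#' @slot slideDim integer length-2, (height, width) in pixels.
#' @slot patchSize integer edge length of a patch in pixels.
#' @slot data data.frame with columns `gridRow`, `gridCol` (0-based),
#'   `isBlank` (logical), and optionally `label`, `nLymph`, `nTumor`, `seed`.
#'
#' @aliases TileManifest-class
#' @exportClass TileManifest
setClass("TileManifest",
  representation(slideId = "character", slideDim = "integer",
                 patchSize = "integer", data = "data.frame"),
  validity = function(object) {
    d <- object@data
    need <- c("gridRow", "gridCol", "isBlank")
    if (!all(need %in% names(d)))
      return("data must have gridRow, gridCol, isBlank columns")
    nr <- object@slideDim[1] %/% object@patchSize
    nc <- object@slideDim[2] %/% object@patchSize
    if (nrow(d) && (any(d$gridRow < 0) || any(d$gridRow >= nr) ||
                    any(d$gridCol < 0) || any(d$gridCol >= nc)))
      return("grid coordinates out of range for the slide dimensions")
    if (anyDuplicated(d[, c("gridRow", "gridCol")]))
      return("duplicate (gridRow, gridCol) entries")
    TRUE
  })

TileManifest <- function(slideId, slideDim, patchSize, data) {
  new("TileManifest", slideId = as.character(slideId),
      slideDim = as.integer(slideDim), patchSize = as.integer(patchSize),
      data = data)
}

#' @describeIn TileManifest the per-patch table (one row per grid cell).
#' @param x a `TileManifest`.
#' @export
manifestData <- function(x) {
  stopifnot(is(x, "TileManifest"))
  x@data
}

#' @describeIn TileManifest slide identifier.
#' @export
slideId <- function(x) {
  stopifnot(is(x, "TileManifest"))
  x@slideId
}

#' @describeIn TileManifest patch edge length in pixels.
#' @export
patchSize <- function(x) {
  stopifnot(is(x, "TileManifest"))
  x@patchSize
}

#' @describeIn TileManifest grid dimensions, c(rows, cols).
#' @export
gridDim <- function(x) {
  stopifnot(is(x, "TileManifest"))
  as.integer(x@slideDim %/% x@patchSize)
}

setMethod("show", "TileManifest", function(object) {
  gd <- gridDim(object)
  cat(sprintf("TileManifest '%s': %dx%d px, %dx%d grid of %d-px patches\n",
              object@slideId, object@slideDim[1], object@slideDim[2],
              gd[1], gd[2], object@patchSize))
  cat(sprintf("  %d patches, %d flagged blank\n",
              nrow(object@data), sum(object@data$isBlank)))
})

setMethod("dim", "TileManifest", function(x) gridDim(x))

#' TILMap: patch-level class map of a slide
#'
#' A grid of per-patch states (`positive`, `negative`, `other`, `blank`)
#' with a rendering palette.
#'
#' @slot slideId character scalar.
#' @slot states character matrix, one entry per grid cell.
#' @slot palette named character vector of colors for the four states.
#' @slot scalePxPerPatch integer, rendered pixels per patch cell.
#'
#' @aliases TILMap-class
#' @exportClass TILMap
setClass("TILMap",
  representation(slideId = "character", states = "matrix",
                 palette = "character", scalePxPerPatch = "integer"),
  validity = function(object) {
    ok <- c("positive", "negative", "other", "blank")
    if (!all(object@states %in% ok))
      return("states must be positive/negative/other/blank")
    if (!all(ok %in% names(object@palette)))
      return("palette must name all four states")
    if (object@scalePxPerPatch < 1L) return("scalePxPerPatch must be >= 1")
    TRUE
  })

#' @describeIn TILMap the state grid (character matrix).
#' @param x a `TILMap`.
#' @export
tilMapStates <- function(x) {
  stopifnot(is(x, "TILMap"))
  x@states
}

setMethod("show", "TILMap", function(object) {
  tab <- table(factor(object@states,
                      levels = c("positive", "negative", "other", "blank")))
  cat(sprintf("TILMap '%s': %dx%d grid\n", object@slideId,
              nrow(object@states), ncol(object@states)))
  print(tab)
})

setMethod("dim", "TILMap", function(x) dim(x@states))

#' MetricsReport: multi-class classifier evaluation
#'
#' Confusion matrix (rows = truth, cols = predicted, class order 0,1,2),
#' overall accuracy and Cohen's kappa, one-vs-rest AUC (macro average, NA
#' when probabilities were not supplied), per-class precision / recall /
#' specificity / F1 and their micro and macro averages.
#'
#' @slot confusion 3x3 count matrix.
#' @slot accuracy,kappa,auc numeric scalars (auc may be NA).
#' @slot perClass data.frame of per-class metrics.
#' @slot micro,macro named numeric vectors (precision, recall, specificity, f1).
#'
#' @aliases MetricsReport-class
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(confusion = "matrix", accuracy = "numeric",
                 kappa = "numeric", auc = "numeric", perClass = "data.frame",
                 micro = "numeric", macro = "numeric"),
  validity = function(object) {
    if (any(object@confusion < 0)) return("confusion counts must be >= 0")
    tot <- sum(object@confusion)
    if (tot > 0 &&
        abs(object@accuracy - sum(diag(object@confusion)) / tot) > 1e-8)
      return("accuracy must equal trace/total")
    if (object@kappa < -1 - 1e-8 || object@kappa > 1 + 1e-8)
      return("kappa must lie in [-1, 1]")
    TRUE
  })

#' @describeIn MetricsReport the 3x3 confusion matrix (rows = truth).
#' @param x a `MetricsReport`.
#' @export
confusionCounts <- function(x) {
  stopifnot(is(x, "MetricsReport"))
  x@confusion
}

#' @describeIn MetricsReport flatten to a named list (for JSON export).
#' @export
metricsAsList <- function(x) {
  stopifnot(is(x, "MetricsReport"))
  list(confusion = unname(apply(x@confusion, 1, as.numeric, simplify = FALSE)),
       accuracy = x@accuracy, kappa = x@kappa, auc = x@auc,
       perClass = x@perClass, micro = as.list(x@micro),
       macro = as.list(x@macro))
}

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  print(object@confusion)
  cat(sprintf("accuracy %.4f  kappa %.4f  auc %s\n", object@accuracy,
              object@kappa,
              if (is.na(object@auc)) "NA" else sprintf("%.4f", object@auc)))
  cat("micro:", paste(names(object@micro),
                      sprintf("%.4f", object@micro), collapse = "  "), "\n")
  cat("macro:", paste(names(object@macro),
                      sprintf("%.4f", object@macro), collapse = "  "), "\n")
})
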