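# TIL scores: the pooled-sum ratio of TIL-positive to tumor-containing
# patches at slide and patient level, cohort kernel-density summaries, and
# patch-level TIL maps.

#' Pooled TIL score over one or more slides
#'
#' The TIL score of a unit (slide, or patient with `m` slides) is the pooled
#' ratio
#' `sum_i N_positive_i / sum_i (N_positive_i + N_negative_i)`,
#' never the mean of per-slide scores. Other/necrotic and blank patches are
#' excluded from both numerator and denominator.
#'
#' @param counts per-slide counts: a two-column matrix/data.frame
#'   (positive, negative) or a list of length-2 vectors.
#' @return List: `m` (number of slides pooled), `nPositive`, `nNegative`,
#'   `score`. Throws a classed error (`PatchTIL_undefinedScore`) when the
#'   denominator is zero - an undefined score is never silently 0.
#' @examples
#' tilScore(list(c(5, 5)))$score            # 0.5
#' tilScore(list(c(2, 2), c(0, 6)))$score   # 0.2 (pooled, not mean 0.25)
#' @export
tilScore <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts)) {
    if (!length(counts)) ptStop("PatchTIL_undefinedScore", "empty count list")
    counts <- do.call(rbind, counts)
  }
  counts <- as.matrix(counts)
  if (!nrow(counts)) ptStop("PatchTIL_undefinedScore", "empty count list")
  if (ncol(counts) != 2 || any(counts < 0))
    stop("counts must be non-negative (positive, negative) pairs")
  nPos <- sum(counts[, 1])
  nNeg <- sum(counts[, 2])
  if (nPos + nNeg == 0)
    ptStop("PatchTIL_undefinedScore",
           "no TIL-positive or TIL-negative patches: TIL score undefined")
  list(m = nrow(counts), nPositive = nPos, nNegative = nNeg,
       score = nPos / (nPos + nNeg))
}

#' Slide- and patient-level TIL scores for a cohort
#'
#' Aggregates patch predictions into per-slide counts, then pools slides per
#' patient. Units whose score is undefined (no tumor-containing
#' patches) get `NA` with a warning; slides missing from the patient map are
#' scored at slide level only, with a warning.
#'
#' @param predictions data.frame with columns `slideId` and `label`
#'   (0/1/2), e.g. from [classifyPatches()].
#' @param patientMap data.frame with columns `slideId`, `patientId`, or NULL
#'   for slide-level scoring only.
#' @return data.frame with columns `unitId`, `level` ("slide"/"patient"),
#'   `m`, `nPositive`, `nNegative`, `nOther`, `score`.
#' @export
scoreCohort <- function(predictions, patientMap = NULL) {
  stopifnot(all(c("slideId", "label") %in% names(predictions)))
  perSlide <- do.call(rbind, lapply(split(predictions, predictions$slideId),
    function(d) data.frame(slideId = d$slideId[1],
                           nPositive = sum(d$label == 0),
                           nNegative = sum(d$label == 1),
                           nOther = sum(d$label == 2))))
  scoreOf <- function(np, nn, unit) {
    tryCatch(np / (np + nn),
             error = function(e) NA_real_)
  }
  rows <- lapply(seq_len(nrow(perSlide)), function(k) {
    s <- perSlide[k, ]
    sc <- tryCatch(tilScore(list(c(s$nPositive, s$nNegative)))$score,
                   PatchTIL_undefinedScore = function(e) {
                     warning(sprintf("slide %s: TIL score undefined", s$slideId))
                     NA_real_
                   })
    data.frame(unitId = s$slideId, level = "slide", m = 1L,
               nPositive = s$nPositive, nNegative = s$nNegative,
               nOther = s$nOther, score = sc)
  })
  out <- do.call(rbind, rows)
  if (!is.null(patientMap)) {
    stopifnot(all(c("slideId", "patientId") %in% names(patientMap)))
    unmapped <- setdiff(perSlide$slideId, patientMap$slideId)
    if (length(unmapped))
      warning("slides without patient mapping (slide-level only): ",
              paste(unmapped, collapse = ", "))
    merged <- merge(perSlide, patientMap, by = "slideId")
    pat <- lapply(split(merged, merged$patientId), function(d) {
      sc <- tryCatch(
        tilScore(d[, c("nPositive", "nNegative")])$score,
        PatchTIL_undefinedScore = function(e) {
          warning(sprintf("patient %s: TIL score undefined", d$patientId[1]))
          NA_real_
        })
      data.frame(unitId = d$patientId[1], level = "patient", m = nrow(d),
                 nPositive = sum(d$nPositive), nNegative = sum(d$nNegative),
                 nOther = sum(d$nOther), score = sc)
    })
    out <- rbind(out, do.call(rbind, pat))
  }
  rownames(out) <- NULL
  out
}

#' Kernel-density summary of cohort TIL scores
#'
#' Gaussian KDE (Scott's rule bandwidth) evaluated on a fixed 512-point grid
#' over \[0, 1\]; returns the curve and the mode (score of highest density).
#'
#' @param scores numeric TIL scores in \[0, 1\]; at least 2 finite values.
#' @param bandwidth optional numeric bandwidth overriding Scott's rule.
#' @param nGrid grid size (default 512).
#' @return List: `x`, `density` (curve over \[0, 1\]), `mode`, `bandwidth`.
#' @export
scoreDensity <- function(scores, bandwidth = NULL, nGrid = 512) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2)
    stop("need at least 2 finite scores for a density estimate")
  bw <- if (!is.null(bandwidth)) bandwidth else
    tryCatch(bw.nrd(scores), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) bw <- 0.01   # degenerate spread fallback
  d <- density(scores, bw = bw, kernel = "gaussian", n = nGrid,
               from = 0, to = 1)
  list(x = d$x, density = d$y, mode = d$x[which.max(d$y)], bandwidth = bw)
}

#' Default TIL-map palette
#'
#' @return Named colors for the four patch states.
#' @export
tilMapPalette <- function() {
  c(positive = "#D62728", negative = "#1F4E9C",
    other = "#2CA02C", blank = "#FFFFFF")
}

#' Build a patch-level TIL map
#'
#' Places each patch prediction at its grid position; blank patches get the
#' blank state. Predictions are keyed by position, so their row order is
#' irrelevant.
#'
#' @param manifest a [TileManifest-class] with up-to-date `isBlank` flags.
#' @param predictions data.frame with `gridRow`, `gridCol`, `label` for
#'   every non-blank patch; a missing prediction is an error naming the
#'   coordinates.
#' @param palette named state colors (default [tilMapPalette()]).
#' @param scalePxPerPatch rendered pixels per patch (default 8).
#' @return A [TILMap-class].
#' @export
buildTILMap <- function(manifest, predictions, palette = tilMapPalette(),
                        scalePxPerPatch = 8) {
  stopifnot(is(manifest, "TileManifest"))
  gd <- gridDim(manifest)
  states <- matrix("blank", gd[1], gd[2])
  d <- manifestData(manifest)
  nb <- d[!d$isBlank, , drop = FALSE]
  key <- paste(predictions$gridRow, predictions$gridCol)
  stateOf <- c(`0` = "positive", `1` = "negative", `2` = "other")
  miss <- !(paste(nb$gridRow, nb$gridCol) %in% key)
  if (any(miss))
    stop("missing predictions for non-blank patches at: ",
         paste(sprintf("(%d,%d)", nb$gridRow[miss], nb$gridCol[miss]),
               collapse = " "))
  for (k in seq_len(nrow(predictions))) {
    i <- predictions$gridRow[k] + 1L
    j <- predictions$gridCol[k] + 1L
    if (i <= gd[1] && j <= gd[2] && !d$isBlank[d$gridRow == i - 1L &
                                               d$gridCol == j - 1L])
      states[i, j] <- stateOf[[as.character(predictions$label[k])]]
  }
  new("TILMap", slideId = slideId(manifest), states = states,
      palette = palette, scalePxPerPatch = as.integer(scalePxPerPatch))
}

#' Render a TIL map to an RGB raster
#'
#' @param map a [TILMap-class].
#' @return (rows * scale) x (cols * scale) x 3 array, values 0-255.
#' @export
renderTILMap <- function(map) {
  stopifnot(is(map, "TILMap"))
  s <- map@scalePxPerPatch
  st <- map@states
  colMat <- grDevices::col2rgb(map@palette[st])   # 3 x (rows*cols)
  out <- array(0, c(nrow(st) * s, ncol(st) * s, 3))
  for (ch in 1:3) {
    plane <- matrix(colMat[ch, ], nrow(st), ncol(st))
    out[, , ch] <- plane[rep(seq_len(nrow(st)), each = s),
                         rep(seq_len(ncol(st)), each = s)]
  }
  out
}

#' Write / read a TIL map
#'
#' `writeTILMap` writes the rendered PNG and a lossless label-grid TSV
#' (suffix `_grid.tsv`); `readTILMapGrid` reconstructs the map from that
#' TSV.
#'
#' @param map a [TILMap-class].
#' @param path PNG output path.
#' @return `writeTILMap`: `path` invisibly; `readTILMapGrid`: a
#'   [TILMap-class].
#' @export
writeTILMap <- function(map, path) {
  stopifnot(is(map, "TILMap"))
  png::writePNG(renderTILMap(map) / 255, path)
  gridPath <- sub("\\.png$", "_grid.tsv", path)
  con <- file(gridPath, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s\t%d", map@slideId, map@scalePxPerPatch), con)
  write.table(map@states, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeTILMap
#' @param gridPath path of a `_grid.tsv` written by `writeTILMap`.
#' @param palette named state colors.
#' @export
readTILMapGrid <- function(gridPath, palette = tilMapPalette()) {
  hdr <- strsplit(sub("^# ", "", readLines(gridPath, n = 1)), "\t")[[1]]
  st <- as.matrix(read.delim(gridPath, skip = 1, header = FALSE))
  dimnames(st) <- NULL
  new("TILMap", slideId = hdr[1], states = st, palette = palette,
      scalePxPerPatch = as.integer(hdr[2]))
}

#' Write cohort scores as TSV
#'
#' @param scores data.frame from [scoreCohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
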