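# Slide IO, non-overlapping tiling into fixed-size patches, and the
# blank-patch filter (mean RGB > 230 and sd < 15 => blank).

#' Read a slide raster (PNG or TIFF)
#'
#' Returns an HxWx3 array on the 0-255 scale. Grayscale images are expanded
#' to three channels; an alpha channel is dropped.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return HxWx3 numeric array, values 0-255.
#' @export
readSlide <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported slide format: ", ext))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write a slide or patch raster (PNG or TIFF)
#'
#' @param pixels HxWx3 array, values 0-255.
#' @param path output path ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
writeSlide <- function(pixels, path) {
  assertPatch(pixels, "slide")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(pixels / 255, path),
    tif = ,
    tiff = tiff::writeTIFF(pixels / 255, path),
    stop("unsupported slide format: ", ext))
  invisible(path)
}

#' Blank-filter parameters
#'
#' A patch is blank when the mean of its per-pixel gray values
#' `(R + G + B) / 3` exceeds `meanThreshold` and their population standard
#' deviation is below `sdThreshold` (strict inequalities).
#'
#' @param meanThreshold intensity threshold (default 230).
#' @param sdThreshold standard-deviation threshold (default 15).
#' @param mode `"gray"` (default): statistics of the per-pixel gray values;
#'   `"channel"`: statistics pooled over all channel values.
#' @return Named list of parameters.
#' @export
blankFilterParams <- function(meanThreshold = 230, sdThreshold = 15,
                              mode = c("gray", "channel")) {
  stopifnot(meanThreshold > 0, meanThreshold < 255,
            sdThreshold > 0, sdThreshold < 255)
  list(meanThreshold = meanThreshold, sdThreshold = sdThreshold,
       mode = match.arg(mode))
}

#' Is a patch blank?
#'
#' @param pixels HxWx3 patch, values 0-255.
#' @param params a [blankFilterParams()] list.
#' @return TRUE when mean gray > meanThreshold and population sd <
#'   sdThreshold.
#' @examples
#' isBlank(array(255, c(150, 150, 3)))   # TRUE
#' isBlank(array(0, c(150, 150, 3)))     # FALSE
#' @export
isBlank <- function(pixels, params = blankFilterParams()) {
  assertPatch(pixels)
  v <- if (params$mode == "gray")
    (pixels[, , 1] + pixels[, , 2] + pixels[, , 3]) / 3 else as.numeric(pixels)
  mean(v) > params$meanThreshold && popSD(v) < params$sdThreshold
}

#' Tile a slide into non-overlapping patches
#'
#' Patch `(i, j)` (0-based, row-major) covers pixel rows
#' `[i * patchSize, (i + 1) * patchSize)` and the analogous columns; partial
#' tiles at the right and bottom edges are dropped, so the grid is
#' `floor(H / patchSize) x floor(W / patchSize)`.
#'
#' @param pixels slide raster, HxWx3 array, values 0-255.
#' @param slideId identifier recorded in the manifest.
#' @param patchSizePx patch edge length (default 150).
#' @return A [TileManifest-class] with all `isBlank` initialized to FALSE.
#' @export
tileSlide <- function(pixels, slideId = "slide", patchSizePx = 150) {
  assertPatch(pixels, "slide")
  d <- dim(pixels)
  if (d[1] < patchSizePx || d[2] < patchSizePx)
    stop(sprintf("slide (%d x %d) is smaller than one %d-px patch",
                 d[1], d[2], patchSizePx))
  nr <- d[1] %/% patchSizePx
  nc <- d[2] %/% patchSizePx
  grid <- expand.grid(gridCol = seq_len(nc) - 1L, gridRow = seq_len(nr) - 1L)
  TileManifest(slideId, d[1:2], patchSizePx,
               data.frame(gridRow = grid$gridRow, gridCol = grid$gridCol,
                          isBlank = FALSE))
}

#' Extract the patch at a grid position
#'
#' @param pixels slide raster.
#' @param gridRow,gridCol 0-based grid coordinates.
#' @param patchSizePx patch edge length (default 150).
#' @return patchSizePx x patchSizePx x 3 array.
#' @export
patchAt <- function(pixels, gridRow, gridCol, patchSizePx = 150) {
  pixels[gridRow * patchSizePx + seq_len(patchSizePx),
         gridCol * patchSizePx + seq_len(patchSizePx), , drop = FALSE]
}

#' Apply the blank filter to every patch of a slide
#'
#' Updates the manifest's `isBlank` flags by running [isBlank()] on each
#' tile of the raster. Idempotent.
#'
#' @param manifest a [TileManifest-class] from [tileSlide()].
#' @param pixels the slide raster the manifest was computed from.
#' @param params a [blankFilterParams()] list.
#' @return The manifest with updated `isBlank` flags.
#' @export
filterPatches <- function(manifest, pixels, params = blankFilterParams()) {
  stopifnot(is(manifest, "TileManifest"))
  d <- manifestData(manifest)
  ps <- patchSize(manifest)
  d$isBlank <- vapply(seq_len(nrow(d)), function(k)
    isBlank(patchAt(pixels, d$gridRow[k], d$gridCol[k], ps), params),
    logical(1))
  manifest@data <- d
  validObject(manifest)
  manifest
}

#' Write / read a tile manifest as TSV
#'
#' The TSV carries a `# slide_id height width patch_size` header comment
#' followed by the per-patch table.
#'
#' @param manifest a [TileManifest-class].
#' @param path file path.
#' @return `writeManifest` returns `path` invisibly; `readManifest` returns
#'   a [TileManifest-class].
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "TileManifest"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s\t%d\t%d\t%d", slideId(manifest),
                     manifest@slideDim[1], manifest@slideDim[2],
                     patchSize(manifest)), con)
  write.table(manifestData(manifest), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  hdr <- strsplit(sub("^# ", "", readLines(path, n = 1)), "\t")[[1]]
  d <- read.delim(path, skip = 1)
  TileManifest(hdr[1], as.integer(hdr[2:3]), as.integer(hdr[4]), d)
}
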