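# Macenko stain normalization: optical-density transform, stain-basis
# estimation from the top-2 OD eigenplane, concentration unmixing, and
# re-rendering against a target profile.

#' Macenko estimation parameters
#'
#' @param beta per-channel OD threshold below which a pixel is treated as
#'   background and excluded from estimation (default 0.15).
#' @param alpha robust angle percentile: the stain directions are taken at
#'   the `alpha` and `100 - alpha` percentiles of the projected angles
#'   (default 1).
#' @param io background intensity (default 240).
#' @param minTissuePixels minimum number of above-threshold pixels required
#'   for estimation (default 100).
#' @param denoiseSigma standard deviation (pixels) of a Gaussian denoise
#'   applied to the OD planes before estimation; 0 disables it (default 1).
#'   Estimation only - normalization re-renders from the un-smoothed image.
#' @param minAngleSpreadDeg minimum spread between the two angle percentiles
#'   before the patch is declared single-stain degenerate (default 1 degree).
#' @param nnls use non-negative least squares for unmixing instead of
#'   clipped unconstrained least squares (default FALSE).
#' @return A named list of parameters.
#' @export
macenkoParams <- function(beta = 0.15, alpha = 1, io = 240,
                          minTissuePixels = 100, denoiseSigma = 1,
                          minAngleSpreadDeg = 1, nnls = FALSE) {
  stopifnot(beta > 0, alpha > 0, alpha < 50, io > 0, minTissuePixels >= 1)
  list(beta = beta, alpha = alpha, io = io,
       minTissuePixels = as.integer(minTissuePixels),
       denoiseSigma = denoiseSigma, minAngleSpreadDeg = minAngleSpreadDeg,
       nnls = isTRUE(nnls))
}

#' RGB to optical density
#'
#' Beer-Lambert transform `OD = -ln((I + 1) / io)`, clipped below at 0.
#' The +1 makes the transform invertible on the quantized 0-255 scale and
#' maps intensity `io - 1` to OD 0.
#'
#' @param pixels HxWx3 array (or any numeric array/vector), values 0-255.
#' @param io background intensity.
#' @return Array of the same shape holding optical densities.
#' @export
rgbToOD <- function(pixels, io = 240) {
  stopifnot(io > 0)
  pmax(-log((pixels + 1) / io), 0)
}

#' Optical density to RGB
#'
#' Inverse of [rgbToOD()]: `I = io * exp(-OD) - 1`, rounded and clipped to
#' `[0, 255]`.
#'
#' @param od numeric array of optical densities.
#' @param io background intensity.
#' @return Array of the same shape with integer-valued intensities.
#' @export
odToRGB <- function(od, io = 240) {
  clip255(round(io * exp(-od) - 1))
}

# Least-squares unmix of an n x 3 OD matrix against a 3 x 2 stain matrix.
# Returns n x 2 concentrations; negatives clipped (or true NNLS on request).
unmixOD <- function(odMat, S, nnls = FALSE) {
  if (!nnls) {
    conc <- odMat %*% t(solve(crossprod(S), t(S)))
    return(pmax(conc, 0))
  }
  # Tiny 2-variable NNLS by case analysis: the unconstrained solution, else
  # the best single-stain fits, else zero.
  StS <- crossprod(S)
  free <- odMat %*% t(solve(StS, t(S)))
  bad <- which(free[, 1] < 0 | free[, 2] < 0)
  conc <- pmax(free, 0)
  if (length(bad)) {
    for (i in bad) {
      od <- odMat[i, ]
      c1 <- max(sum(od * S[, 1]) / StS[1, 1], 0)
      c2 <- max(sum(od * S[, 2]) / StS[2, 2], 0)
      r1 <- sum((od - S[, 1] * c1)^2)
      r2 <- sum((od - S[, 2] * c2)^2)
      conc[i, ] <- if (r1 <= r2) c(c1, 0) else c(0, c2)
    }
  }
  conc
}

#' Per-pixel stain concentrations of a patch
#'
#' Transforms a patch to optical density and solves `OD = S c` for the
#' hematoxylin and eosin concentrations of every pixel by least squares
#' (negatives clipped to zero).
#'
#' @param pixels HxWx3 patch, values 0-255.
#' @param profile a [StainProfile-class] supplying the stain matrix and io.
#' @param nnls use non-negative least squares (default FALSE).
#' @return List with `h` and `e`: HxW concentration matrices.
#' @export
stainConcentrations <- function(pixels, profile = defaultStainProfile(),
                                nnls = FALSE) {
  assertPatch(pixels)
  d <- dim(pixels)
  od <- rgbToOD(pixels, backgroundIntensity(profile))
  conc <- unmixOD(matrix(od, ncol = 3), stainMatrix(profile), nnls)
  list(h = matrix(conc[, 1], d[1], d[2]),
       e = matrix(conc[, 2], d[1], d[2]))
}

#' Estimate an H&E stain profile from a patch (Macenko)
#'
#' Background pixels (any OD channel below `beta`) are discarded; the
#' remaining OD pixels are eigen-decomposed, projected onto the top-2
#' eigenplane, and the `alpha` / `100 - alpha` angle percentiles are
#' back-projected to two unit stain vectors. The vector with the larger
#' red-channel OD component is assigned to hematoxylin. Per-stain scales are
#' the 99th-percentile unmixed concentrations.
#'
#' @param pixels HxWx3 patch, values 0-255.
#' @param params a [macenkoParams()] list.
#' @return A [StainProfile-class].
#'   Throws a classed error (`PatchTIL_degenerateInput`) when fewer than
#'   `minTissuePixels` pixels survive the OD threshold or when the angle
#'   spread indicates a single stain.
#' @export
estimateStainProfile <- function(pixels, params = macenkoParams()) {
  assertPatch(pixels)
  d <- dim(pixels)
  od <- rgbToOD(pixels, params$io)
  if (params$denoiseSigma > 0) {
    for (ch in 1:3)
      od[, , ch] <- as.matrix(EBImage::gblur(EBImage::Image(od[, , ch]),
                                             sigma = params$denoiseSigma))
  }
  odMat <- matrix(od, ncol = 3)
  tissue <- odMat[rowSums(odMat > params$beta) == 3L, , drop = FALSE]
  if (nrow(tissue) < params$minTissuePixels)
    ptStop("PatchTIL_degenerateInput",
           "only %d tissue pixels above OD threshold (need >= %d)",
           nrow(tissue), params$minTissuePixels)
  ev <- eigen(cov(tissue), symmetric = TRUE)
  V <- ev$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) if (sum(V[, j]) < 0) V[, j] <- -V[, j]
  proj <- tissue %*% V
  phi <- atan2(proj[, 2], proj[, 1])
  q <- quantile(phi, c(params$alpha, 100 - params$alpha) / 100, names = FALSE)
  if (abs(diff(q)) < params$minAngleSpreadDeg * pi / 180)
    ptStop("PatchTIL_degenerateInput",
           "angle percentiles nearly coincide (spread %.3f deg): single stain",
           abs(diff(q)) * 180 / pi)
  M <- cbind(V %*% c(cos(q[1]), sin(q[1])),
             V %*% c(cos(q[2]), sin(q[2])))
  M <- abs(M)                       # stain vectors live in the positive octant
  M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  if (M[1, 1] < M[1, 2]) M <- M[, 2:1]    # hematoxylin has the larger red OD
  conc <- unmixOD(matrix(rgbToOD(pixels, params$io), ncol = 3), M,
                  params$nnls)
  maxC <- apply(conc, 2, quantile, probs = 0.99, names = FALSE)
  maxC[maxC <= 0] <- 1e-6
  StainProfile(M, maxConcentration = maxC, io = params$io)
}

#' Normalize a patch to a target stain profile
#'
#' Estimates the source stain profile (unless one is supplied), unmixes the
#' patch into stain concentrations, rescales each stain by
#' `target max / source 99th percentile`, and re-renders with the target
#' stain matrix and background intensity. Degenerate inputs (blank or
#' single-stain patches) are returned unchanged with attribute
#' `passThrough = TRUE`.
#'
#' @param pixels HxWx3 patch, values 0-255.
#' @param target target [StainProfile-class] (default the canonical H&E
#'   reference).
#' @param params a [macenkoParams()] list.
#' @param source optional known source [StainProfile-class]; skips
#'   estimation.
#' @return Normalized patch (same shape, values 0-255). Attribute
#'   `passThrough` is TRUE when the input was returned unchanged.
#' @export
normalizePatch <- function(pixels, target = defaultStainProfile(),
                           params = macenkoParams(), source = NULL) {
  assertPatch(pixels)
  if (is.null(source)) {
    source <- tryCatch(estimateStainProfile(pixels, params),
                       PatchTIL_degenerateInput = function(e) NULL)
    if (is.null(source)) {
      out <- pixels
      attr(out, "passThrough") <- TRUE
      return(out)
    }
  }
  d <- dim(pixels)
  od <- matrix(rgbToOD(pixels, backgroundIntensity(source)), ncol = 3)
  conc <- unmixOD(od, stainMatrix(source), params$nnls)
  scale <- maxConcentration(target) / maxConcentration(source)
  conc <- sweep(conc, 2, scale, "*")
  odNew <- conc %*% t(stainMatrix(target))
  out <- array(odToRGB(odNew, backgroundIntensity(target)), d)
  attr(out, "passThrough") <- FALSE
  out
}

#' Write / read a StainProfile as JSON
#'
#' @param profile a [StainProfile-class].
#' @param path file path.
#' @return `writeStainProfile` returns `path` invisibly; `readStainProfile`
#'   returns a [StainProfile-class].
#' @export
writeStainProfile <- function(profile, path) {
  stopifnot(is(profile, "StainProfile"))
  jsonlite::write_json(
    list(stain_matrix = unname(apply(stainMatrix(profile), 1, as.numeric,
                                     simplify = FALSE)),
         max_concentration = maxConcentration(profile),
         io = backgroundIntensity(profile)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeStainProfile
#' @export
readStainProfile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  M <- x$stain_matrix
  if (is.list(M)) M <- do.call(rbind, M)
  StainProfile(M, maxConcentration = x$max_concentration, io = x$io)
}
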