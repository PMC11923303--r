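refProfile <- defaultStainProfile()

test_that("optical-density transform matches closed forms and round-trips", {
  expect_equal(as.numeric(rgbToOD(array(239, c(1, 1, 3)))), rep(0, 3))
  expect_equal(as.numeric(rgbToOD(array(0, c(1, 1, 3)))),
               rep(log(240), 3), tolerance = 1e-12)
  # round trip exact on the representable intensity range [0, io - 1]
  set.seed(1)
  x <- array(sample(0:239, 150 * 150 * 3, replace = TRUE), c(150, 150, 3))
  expect_lte(max(abs(odToRGB(rgbToOD(x)) - x)), 1)
})

test_that("stain profile estimation recovers the rendering basis", {
  for (k in 1:3) {
    p <- generatePatch(patchSpec(nLymphocytes = 6, nTumorCells = 2,
                                 seed = 100 + k))
    est <- estimateStainProfile(p$pixels)
    expect_lt(stainAngleError(stainMatrix(est), stainMatrix(refProfile)), 2)
  }
  # noisy fixtures: within 5 degrees
  for (k in 1:3) {
    p <- generatePatch(patchSpec(nLymphocytes = 6, nTumorCells = 2,
                                 noiseSd = 8, seed = 200 + k))
    est <- estimateStainProfile(p$pixels)
    expect_lt(stainAngleError(stainMatrix(est), stainMatrix(refProfile)), 5)
  }
})

test_that("degenerate inputs are flagged, not silently estimated", {
  expect_error(estimateStainProfile(grayPatch(255)),
               class = "PatchTIL_degenerateInput")
  # single stain spanning varied concentrations
  S <- stainMatrix(refProfile)
  hc <- matrix(seq(0.2, 1.2, length.out = 150 * 150), 150)
  od <- array(0, c(150, 150, 3))
  for (ch in 1:3) od[, , ch] <- hc * S[ch, 1]
  single <- odToRGB(od)
  expect_error(estimateStainProfile(single),
               class = "PatchTIL_degenerateInput")
  # blank patch passes through normalization unchanged
  out <- normalizePatch(grayPatch(250))
  expect_true(attr(out, "passThrough"))
  expect_equal(as.numeric(out), as.numeric(grayPatch(250)))
})

test_that("normalization is a fixed point on already-normalized patches", {
  p <- generatePatch(patchSpec(nLymphocytes = 6, nTumorCells = 2, seed = 11))
  # target = the patch's own profile: change stays within quantization
  own <- estimateStainProfile(p$pixels)
  expect_lt(mean(abs(normalizePatch(p$pixels, own) - p$pixels)), 2)
  # approximate idempotence against the canonical target
  n1 <- normalizePatch(p$pixels)
  n2 <- normalizePatch(n1)
  expect_lt(mean(abs(n2 - n1)), 2)
  expect_true(all(n1 >= 0 & n1 <= 255))
})

test_that("normalization pulls differently stained copies together", {
  alt <- StainProfile(matrix(c(0.49, 0.77, 0.41, 0.10, 0.85, 0.52), nrow = 3),
                      maxConcentration = c(1.9705, 1.0308))
  a <- generatePatch(patchSpec(nLymphocytes = 5, nTumorCells = 2, seed = 21))
  b <- generatePatch(patchSpec(nLymphocytes = 5, nTumorCells = 2, seed = 21,
                               stainProfile = alt))
  before <- mean(abs(a$pixels - b$pixels))
  after <- mean(abs(normalizePatch(a$pixels) - normalizePatch(b$pixels)))
  expect_gt(before / after, 5)
})

test_that("stain profiles serialize to JSON and back", {
  est <- estimateStainProfile(
    generatePatch(patchSpec(nLymphocytes = 5, nTumorCells = 2,
                            seed = 31))$pixels)
  path <- withr::local_tempfile(fileext = ".json")
  writeStainProfile(est, path)
  back <- readStainProfile(path)
  expect_equal(stainMatrix(back), stainMatrix(est), tolerance = 1e-12)
  expect_equal(maxConcentration(back), maxConcentration(est),
               tolerance = 1e-12)
  expect_equal(backgroundIntensity(back), 240)
})

test_that("StainProfile validity rejects malformed bases", {
  expect_error(StainProfile(matrix(1, 3, 3)), "3x2|dims|columns")
  expect_error(StainProfile(matrix(c(1, 0, 0, 0, -1, 0), nrow = 3)),
               "non-negative")
  expect_error(StainProfile(stainMatrix(refProfile),
                            maxConcentration = c(0, 1)), "positive")
})
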