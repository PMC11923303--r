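test_that("generated patches carry the rule-consistent ground-truth label", {
  p <- generatePatch(patchSpec(nLymphocytes = 3, nTumorCells = 1, seed = 1))
  expect_equal(p$label, 0L)
  expect_equal(sum(p$cells$cellClass == "lymphocyte"), 3)
  expect_equal(sum(p$cells$cellClass == "tumor"), 1)

  p0 <- generatePatch(patchSpec(nLymphocytes = 0, nTumorCells = 0, seed = 2,
                                background = "white"))
  expect_equal(p0$label, 2L)
  expect_true(isBlank(p0$pixels))

  pl <- generatePatch(patchSpec(nLymphocytes = 10, nTumorCells = 0, seed = 3))
  expect_equal(pl$label, 2L)   # no tumor cells, whatever the lymphocyte count
})

test_that("patch generation is deterministic and shape/range-correct", {
  spec <- patchSpec(nLymphocytes = 4, nTumorCells = 2, noiseSd = 6, seed = 42)
  a <- generatePatch(spec)
  b <- generatePatch(spec)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$cells, b$cells)
  expect_equal(dim(a$pixels), c(150, 150, 3))
  expect_true(all(a$pixels >= 0 & a$pixels <= 255))
  c <- generatePatch(patchSpec(nLymphocytes = 4, nTumorCells = 2,
                               noiseSd = 6, seed = 43))
  expect_false(identical(a$pixels, c$pixels))
})

test_that("cell geometry honors the class morphology contract", {
  p <- generatePatch(patchSpec(nLymphocytes = 5, nTumorCells = 2, seed = 9))
  ly <- p$cells[p$cells$cellClass == "lymphocyte", ]
  tu <- p$cells[p$cells$cellClass == "tumor", ]
  expect_true(all(ly$area > 0) && all(tu$area > 0))
  expect_true(max(ly$area) < min(tu$area))        # separable by area
  expect_true(all(p$cells$circularity <= 1.1))
  expect_true(all(ly$circularity > 0.9))          # disks are round
  expect_true(all(ly$meanHConc >= 0.8 & ly$meanHConc <= 1.2))
  expect_true(all(tu$meanHConc >= 0.4 & tu$meanHConc <= 0.8))
})

test_that("infeasible placement raises a capacity error", {
  expect_error(generatePatch(patchSpec(nLymphocytes = 0, nTumorCells = 30,
                                       seed = 1)),
               class = "PatchTIL_capacityError")
})

test_that("Beer-Lambert rendering round-trips the programmed concentrations", {
  p <- generatePatch(patchSpec(nLymphocytes = 4, nTumorCells = 1, seed = 5))
  conc <- stainConcentrations(p$pixels)
  expect_lt(max(abs(conc$h - p$hConcTrue)), 0.05)
  expect_lt(max(abs(conc$e - p$eConcTrue)), 0.05)
})

test_that("generateSlide separates blank and tissue patches as recorded", {
  sl <- generateSlide(slideSpec(4, 4, tissueFraction = 0, seed = 1))
  expect_true(all(manifestData(sl$manifest)$isBlank))

  sl2 <- generateSlide(slideSpec(4, 4, tissueFraction = 1,
                                 labelProbs = c(1, 0, 0),
                                 posLymph = c(3, 3), posTumor = c(1, 1),
                                 seed = 2))
  md <- manifestData(sl2$manifest)
  expect_true(all(!md$isBlank))
  expect_true(all(md$label == 0L))
  expect_equal(dim(sl2$pixels), c(600, 600, 3))

  # blank consistency: manifest flags equal a brute-force re-scan
  sl3 <- generateSlide(slideSpec(5, 5, tissueFraction = 0.6, seed = 7))
  md3 <- manifestData(sl3$manifest)
  rescan <- vapply(seq_len(nrow(md3)), function(k)
    isBlank(patchAt(sl3$pixels, md3$gridRow[k], md3$gridCol[k])), logical(1))
  expect_identical(md3$isBlank, rescan)
  # ground-truth labels always match the rule applied to true counts
  tis <- md3[!md3$isBlank, ]
  expect_identical(tis$label, as.integer(ruleLabel(tis$nLymph, tis$nTumor)))
})

test_that("dataset label counts follow the requested ratio", {
  counts <- PatchTIL:::ratioCounts(400, c(1, 1.5, 1.5))
  expect_identical(counts, c(100L, 150L, 150L))
  c4 <- PatchTIL:::ratioCounts(4, c(1, 1, 1))
  expect_equal(sum(c4), 4)
  expect_lte(diff(range(c4)), 1)

  ds <- generateLabeledDataset(20, seed = 1)
  expect_identical(as.integer(table(factor(ds$labels, levels = 0:2))),
                   PatchTIL:::ratioCounts(20, c(1, 1.5, 1.5)))
  expect_identical(ds$labels, ds$manifest$label)
  expect_identical(as.integer(ruleLabel(ds$manifest$nLymph,
                                        ds$manifest$nTumor)),
                   ds$manifest$label)
  # two seeds: identical label counts, different pixels
  ds2 <- generateLabeledDataset(20, seed = 2)
  expect_identical(table(ds$labels), table(ds2$labels))
  expect_false(identical(ds$patches[[1]], ds2$patches[[1]]))
  expect_error(generateLabeledDataset(2), "nTotal")
})

test_that("dataset export writes PNG patches plus a labels manifest", {
  ds <- generateLabeledDataset(6, seed = 3)
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  expect_length(list.files(dir, pattern = "\\.png$"), 6)
  lab <- read.delim(file.path(dir, "labels.tsv"))
  expect_identical(lab$label, ds$manifest$label)
  back <- readSlide(file.path(dir, "patch_00000.png"))
  expect_equal(back, ds$patches[[1]], ignore_attr = TRUE)
})
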