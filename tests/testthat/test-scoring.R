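test_that("the TIL score is the pooled ratio, not the mean of ratios", {
  expect_equal(tilScore(list(c(5, 5)))$score, 0.5)
  pooled <- tilScore(list(c(2, 2), c(0, 6)))
  expect_equal(pooled$score, 0.2)          # mean of per-slide scores were 0.25
  expect_equal(pooled$m, 2L)
  expect_error(tilScore(list(c(0, 0))), class = "PatchTIL_undefinedScore")
  expect_error(tilScore(list()), class = "PatchTIL_undefinedScore")
  expect_error(tilScore(list(c(-1, 2))), "non-negative")

  # brute-force oracle on random count lists
  set.seed(21)
  for (rep in 1:50) {
    counts <- matrix(sample(0:30, 2 * sample(1:5, 1), replace = TRUE),
                     ncol = 2)
    if (sum(counts) == 0) next
    expect_identical(tilScore(counts)$score,
                     sum(counts[, 1]) / sum(counts))
  }
})

test_that("score responds monotonically to counts and ignores other patches", {
  base <- tilScore(list(c(4, 6)))$score
  expect_gte(tilScore(list(c(5, 6)))$score, base)
  expect_lte(tilScore(list(c(4, 7)))$score, base)
  # other/necrotic and blank patches never enter the score
  preds <- data.frame(slideId = "s", label = c(0, 0, 1, 2, 2, 2))
  preds2 <- data.frame(slideId = "s", label = c(0, 0, 1))
  expect_equal(scoreCohort(preds)$score, scoreCohort(preds2)$score)
})

test_that("cohort scoring pools slides per patient by the score formula", {
  preds <- rbind(
    data.frame(slideId = "A", label = rep(c(0, 1), c(3, 1))),
    data.frame(slideId = "B", label = rep(c(0, 1), c(1, 3))))
  pm <- data.frame(slideId = c("A", "B"), patientId = c("P", "P"))
  sc <- scoreCohort(preds, pm)
  expect_equal(sc$score[sc$level == "patient"], 0.5)   # 4 / 8 pooled
  expect_equal(sc$m[sc$level == "patient"], 2L)
  expect_setequal(sc$unitId[sc$level == "slide"], c("A", "B"))

  # all-other cohort: undefined scores surface as NA with warnings
  allOther <- data.frame(slideId = c("A", "A"), label = c(2, 2))
  warns <- capture_warnings(sc2 <- scoreCohort(allOther, pm))
  expect_true(all(grepl("undefined", warns)))   # slide and patient level
  expect_true(all(is.na(sc2$score)))

  # unmapped slides are scored at slide level with a warning
  expect_warning(sc3 <- scoreCohort(preds,
                                    data.frame(slideId = "A",
                                               patientId = "P")),
                 "without patient mapping")
  expect_true("B" %in% sc3$unitId[sc3$level == "slide"])
})

test_that("density summary finds modes and integrates to one", {
  set.seed(31)
  tight <- 0.3 + rnorm(100, 0, 0.005)
  d <- scoreDensity(tight)
  expect_equal(d$mode, 0.3, tolerance = 0.02)
  expect_equal(sum(d$density) * diff(d$x[1:2]), 1, tolerance = 0.01)

  bimodal <- c(0.2 + rnorm(200, 0, 0.01), 0.8 + rnorm(200, 0, 0.01))
  db <- scoreDensity(bimodal)
  y <- db$density
  localMax <- which(diff(sign(diff(y))) == -2) + 1
  peaks <- db$x[localMax[y[localMax] > max(y) * 0.2]]
  expect_equal(sum(abs(peaks - 0.2) < 0.05), 1)
  expect_equal(sum(abs(peaks - 0.8) < 0.05), 1)
  expect_error(scoreDensity(0.5), "at least 2")
})

test_that("TIL maps are position-keyed and round-trip through TSV", {
  sl <- generateSlide(slideSpec(3, 3, tissueFraction = 0.6, seed = 41))
  manifest <- filterPatches(tileSlide(sl$pixels, "m"), sl$pixels)
  preds <- classifyPatches(manifest, sl$pixels, ruleBackend())
  map <- buildTILMap(manifest, preds)
  truth <- manifestData(sl$manifest)
  stateOf <- c(`0` = "positive", `1` = "negative", `2` = "other")
  for (k in seq_len(nrow(truth))) {
    want <- if (truth$isBlank[k]) "blank" else stateOf[[as.character(truth$label[k])]]
    expect_identical(tilMapStates(map)[truth$gridRow[k] + 1,
                                       truth$gridCol[k] + 1], want)
  }
  # permuting prediction rows changes nothing
  map2 <- buildTILMap(manifest, preds[rev(seq_len(nrow(preds))), ])
  expect_identical(tilMapStates(map2), tilMapStates(map))
  # missing prediction errors with coordinates
  expect_error(buildTILMap(manifest, preds[-1, ]), "\\(\\d+,\\d+\\)")

  png <- withr::local_tempfile(fileext = ".png")
  writeTILMap(map, png)
  back <- readTILMapGrid(sub("\\.png$", "_grid.tsv", png))
  expect_identical(tilMapStates(back), tilMapStates(map))
  rendered <- renderTILMap(map)
  expect_equal(dim(rendered), c(24, 24, 3))

  # all-blank slide renders a uniform blank map
  blankSlide <- generateSlide(slideSpec(2, 2, tissueFraction = 0, seed = 42))
  bm <- filterPatches(tileSlide(blankSlide$pixels, "b"), blankSlide$pixels)
  bmap <- buildTILMap(bm, classifyPatches(bm, blankSlide$pixels,
                                          ruleBackend()))
  expect_true(all(tilMapStates(bmap) == "blank"))
})
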