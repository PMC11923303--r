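# Shared helpers for synthetic fixtures.

angleErrorDeg <- function(a, b) {
  acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
}

# Max angular error (degrees) of an estimated stain matrix vs the truth.
stainAngleError <- function(estimated, truth) {
  max(angleErrorDeg(estimated[, 1], truth[, 1]),
      angleErrorDeg(estimated[, 2], truth[, 2]))
}

# Draw per-class cell counts consistent with a target label.
countsForLabel <- function(label) {
  switch(as.character(label),
         "0" = c(sample(3:8, 1), sample(1:3, 1)),
         "1" = c(sample(0:2, 1), sample(1:3, 1)),
         "2" = c(sample(0:5, 1), 0L))
}

# A uniform gray patch.
grayPatch <- function(value, size = 150) array(value, c(size, size, 3))
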