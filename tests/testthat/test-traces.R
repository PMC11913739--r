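test_that("dF/F normalization matches hand-computed values", {
  expect_equal(dffNormalize(c(5, 5, 5, 5)), c(0, 0, 0, 0))
  expect_equal(dffNormalize(c(1, 3)), c(-0.5, 0.5), tolerance = 1e-12)
  ## excluded frames are dropped from the mean but still transformed
  expect_equal(dffNormalize(c(1, 3, 100), c(FALSE, FALSE, TRUE)),
               c(-0.5, 0.5, 49), tolerance = 1e-12)
  expect_error(dffNormalize(c(-1, -3)), "positive")
})

test_that("dF/F normalization is scale invariant and matrix-aware", {
  set.seed(1)
  x <- abs(rnorm(50)) + 1
  expect_equal(dffNormalize(x), dffNormalize(7.3 * x), tolerance = 1e-12)
  m <- rbind(a = x, b = 2 * x, c = rep(0, 50))
  expect_warning(out <- dffNormalize(m), "non-positive")
  expect_equal(out["a", ], out["b", ], tolerance = 1e-12)
  expect_true(all(is.na(out["c", ])))
})

test_that("annulus neuropil averages the right pixels", {
  ## 200 x 200 um grid at 2 um pixels, annulus centered mid-field
  mk <- function(fill) array(fill, c(100, 100, 3))
  ctr <- c(100, 100)
  expect_equal(annulusNeuropil(mk(4.5), ctr, pixel_size = 2),
               rep(4.5, 3))
  ## intensity only inside r < 20 um contributes nothing
  st <- mk(0)
  pc <- expand.grid(row = 1:100, col = 1:100)
  d <- sqrt(((pc$col - 0.5) * 2 - 100)^2 + ((pc$row - 0.5) * 2 - 100)^2)
  inner <- which(d < 20)
  for (f in 1:3) st[cbind(pc$row[inner], pc$col[inner], f)] <- 1
  expect_equal(annulusNeuropil(st, ctr, pixel_size = 2), rep(0, 3))
  ## excluding half the annulus leaves the mean of the rest
  st9 <- mk(9)
  left <- which((pc$col - 0.5) * 2 < 100)
  expect_equal(annulusNeuropil(st9, ctr, pixel_size = 2, exclude = left),
               rep(9, 3))
  expect_error(annulusNeuropil(mk(1), c(1e4, 1e4), pixel_size = 2),
               "no pixels")
})

test_that("activity rate integrates the deconvolved signal", {
  expect_equal(activityRate(c(0, 2, 0), 10), 2 / 3, tolerance = 1e-12)
  expect_equal(activityRate(rep(0, 30), 15), 0)
  expect_equal(activityRate(rep(1, 450), 30), 1)
  m <- rbind(c(0, 2, 0), c(1, 1, 1))
  expect_equal(activityRate(m, 10), c(2 / 3, 1), tolerance = 1e-12)
  expect_error(activityRate(numeric(0), 10), "frames")
})

test_that("seizure alignment subtracts the pre-onset baseline", {
  tt <- seq(0, 20, by = 0.1)
  tr <- rep(3, length(tt))
  expect_equal(alignToSeizure(tr, tt, onset = 10), rep(0, length(tt)))
  step <- 3 + 2 * (tt >= 10)
  al <- alignToSeizure(step, tt, onset = 10)
  expect_equal(unique(al[tt >= 10]), 2)
  ## adding a constant leaves the aligned trace unchanged
  expect_equal(alignToSeizure(step + 11.5, tt, onset = 10), al,
               tolerance = 1e-12)
  expect_error(alignToSeizure(tr, tt, onset = 0.2), "baseline")
})

test_that("recruitment delay finds the threshold crossing", {
  tt <- seq(0, 30, by = 1 / 15)
  step <- as.numeric(tt >= 12)
  expect_equal(recruitmentDelay(step, tt, 10, 20, frac = 0.65), 2,
               tolerance = 1 / 15)
  ## linear ramp onset -> offset crosses frac at frac * duration
  ramp <- pmin(pmax((tt - 10) / 10, 0), 1)
  expect_equal(recruitmentDelay(ramp, tt, 10, 20, frac = 0.65), 6.5,
               tolerance = 1 / 15)
  expect_equal(recruitmentDelay(ramp, tt, 10, 20, frac = 0.85), 8.5,
               tolerance = 1 / 15)
  ## already at max -> zero delay
  expect_equal(recruitmentDelay(rep(2, length(tt)), tt, 10, 20, frac = 0.65),
               0, tolerance = 1 / 15)
})

test_that("recruitment delay is monotone in the threshold fraction", {
  set.seed(3)
  tt <- seq(0, 30, by = 1 / 15)
  for (i in 1:20) {
    r <- cumsum(runif(length(tt)))        # random monotone rise
    tr <- r / max(r)
    d1 <- recruitmentDelay(tr, tt, 5, 25, frac = 0.65)
    d2 <- recruitmentDelay(tr, tt, 5, 25, frac = 0.85)
    expect_gte(d2, d1)
  }
})

test_that("cross-correlation lag recovers constructed shifts", {
  set.seed(4)
  a <- as.numeric(stats::filter(rnorm(400), 0.9, method = "recursive"))
  expect_equal(xcorrLag(a, a, 20)$lag, 0)
  for (k in c(3L, 11L, -7L)) {
    b <- if (k >= 0) c(rep(0, k), a[seq_len(400 - k)]) else
      c(a[(1 - k):400], rep(0, -k))
    res <- xcorrLag(a, b, 20)
    expect_equal(res$lag_frames, k)
    expect_equal(res$lag, k / 20)
  }
  s <- sin(seq(0, 8 * pi, length.out = 300))
  expect_equal(xcorrLag(s, s, 20)$correlation, 1, tolerance = 1e-9)
  expect_true(is.na(xcorrLag(rep(1, 300), s, 20)$lag))
  expect_error(xcorrLag(a[1:50], a[1:50], 20, max_lag = 2), "longer")
})

test_that("nearest excitatory neighbour respects the search radius", {
  rois <- data.frame(roi_id = 1:4,
                     x = c(0, 50, 30, 150), y = c(0, 0, 0, 0),
                     is_inhibitory = c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(nearestExcitatory(1, rois[-3, ]), 2L)
  expect_identical(nearestExcitatory(1, rois), 3L)
  expect_true(is.na(nearestExcitatory(1, rois[c(1, 4), ])))
})

test_that("overlap filtering drops contaminated excitatory ROIs", {
  rois <- data.frame(roi_id = 1:4,
                     is_inhibitory = c(TRUE, FALSE, FALSE, FALSE))
  masks <- list(1:50,
                101:200,               # no overlap: kept
                c(1:10, 201:290),      # 10 of 100 shared (10%): dropped
                c(1:4, 301:396))       # 4 of 100 shared (4%): kept
  out <- overlapFilter(rois, masks)
  expect_identical(out$roi_id, c(1L, 2L, 4L))
})
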