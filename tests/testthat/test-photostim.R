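test_that("target disk extraction averages the right pixels", {
  st <- array(2.5, c(50, 50, 4))               # 100 x 100 um at 2 um pixels
  out <- extractTargetTraces(st, rbind(c(30, 30), c(70, 70)), pixel_size = 2)
  expect_equal(out, matrix(2.5, 2, 4))
  ## a disk over a constant region on a zero background reads that constant
  st0 <- array(0, c(50, 50, 2))
  st0[10:20, 10:20, ] <- 7                     # x in (18,40], y likewise
  out2 <- extractTargetTraces(st0, rbind(c(29, 29), c(80, 80)),
                              pixel_size = 2)
  expect_equal(out2[1, ], c(7, 7))
  expect_equal(out2[2, ], c(0, 0))             # disjoint targets independent
  expect_error(extractTargetTraces(st0, cbind(500, 500), pixel_size = 2),
               "outside")
})

test_that("response magnitude is post-window minus pre-window", {
  tt <- seq(0, 4, by = 0.1)
  expect_equal(responseMagnitude(rep(2, 41), tt, 2, 2.2), 0)
  step <- as.numeric(tt > 2.2)
  expect_equal(responseMagnitude(step, tt, 2, 2.2), 1)
  ## symmetric pre/post values cancel: pre mean 3, post mean 3
  tr <- numeric(41)
  tr[tt >= 1.5 & tt < 2] <- c(1, 2, 3, 4, 5)
  tr[tt > 2.2 & tt <= 2.7] <- c(5, 4, 3, 2, 1)
  expect_equal(responseMagnitude(tr, tt, 2, 2.2), 0, tolerance = 1e-12)
})

test_that("response magnitude is linear and shift invariant", {
  set.seed(5)
  tt <- seq(0, 6, by = 1 / 15)
  a <- rnorm(length(tt))
  b <- rnorm(length(tt))
  ra <- responseMagnitude(a, tt, 3, 3.25)
  rb <- responseMagnitude(b, tt, 3, 3.25)
  expect_equal(responseMagnitude(a + b, tt, 3, 3.25), ra + rb,
               tolerance = 1e-12)
  expect_equal(responseMagnitude(a + 42, tt, 3, 3.25), ra, tolerance = 1e-9)
})

test_that("decay constant matches hand enumeration and the closed form", {
  tt <- seq(0, 0.5, by = 0.1)
  expect_equal(decayConstant(c(1, 0.8, 0.7, 0.5, 0.4, 0.3), tt, 0), 0.3)
  ## monotone increasing post segment never crosses: undefined
  expect_true(is.na(decayConstant(seq(1, 2, length.out = 6), tt, 0)))
})

test_that("z-scoring uses the neuron's baseline distribution", {
  expect_equal(zscoreToBaseline(2, c(1, 2, 3)), 0)
  expect_equal(zscoreToBaseline(3, c(1, 2, 3)), 1, tolerance = 1e-12)
  z <- zscoreToBaseline(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_true(all(is.na(zscoreToBaseline(1:3, c(2, 2, 2)))))
  expect_true(all(is.na(zscoreToBaseline(1:3, 5))))
})

test_that("response CV is sample SD over mean", {
  expect_equal(responseCV(c(2, 2, 2)), 0)
  expect_equal(responseCV(c(1, 3)), sqrt(2) / 2, tolerance = 1e-12)
  set.seed(6)
  x <- rnorm(20, 5)
  expect_equal(responseCV(3.7 * x), responseCV(x), tolerance = 1e-12)
  expect_true(is.na(responseCV(c(-1, 1))))
})

test_that("non-target selection enforces the exclusion zone", {
  rois <- data.frame(roi_id = 1:4, x = c(0, 15, 25, 20), y = c(0, 0, 0, 0),
                     is_target = c(TRUE, FALSE, FALSE, FALSE))
  kept <- selectNontargets(rois)$roi_id
  expect_false(2 %in% kept)   # 15 um: inside the zone
  expect_true(3 %in% kept)    # 25 um: retained
  expect_false(4 %in% kept)   # exactly 20 um: boundary-inclusive exclusion
})

test_that("pre-stimulation level averages the window before onset", {
  tt <- seq(0, 4, by = 0.01)
  expect_equal(prestimLevel(rep(1.3, length(tt)), tt, 2), 1.3)
  ramp <- pmin(pmax((tt - 1.5) / 0.5, 0), 1)
  expect_equal(prestimLevel(ramp, tt, 2), 0.5, tolerance = 0.02)
  expect_true(is.na(prestimLevel(ramp, tt, 2,
                                 excluded = rep(TRUE, length(tt)))))
})

test_that("widefield response ignores shutter-closed frames", {
  tt <- seq(0, 4, by = 0.1)
  expect_equal(widefieldResponse(rep(1, 41), tt, 2, 2.3), 0)
  step <- as.numeric(tt > 2.3)
  expect_equal(widefieldResponse(step, tt, 2, 2.3), 1)
  tr <- rep(3, 41)
  tr[tt >= 2 & tt <= 2.3] <- -50      # shutter artifact must not leak
  tr[tt > 2.3] <- 5
  expect_equal(widefieldResponse(tr, tt, 2, 2.3), 2)
})

test_that("interictal target responses recover the configured gain", {
  ## zero noise and background: mean measured response is the evoked
  ## amplitude attenuated only by the kernel decay over the post window;
  ## responses at two gains scale exactly linearly
  mk <- function(g) quickConfig(noise_sd = 0, transient_rate = 0,
                                shared_fluctuation_sd = 0,
                                stim_global_amp = 0, coupling_weight = 0,
                                stim_gain_interictal = g, duration = 100,
                                seed = 11L)
  r_of <- function(g) {
    expt <- addDff(simulateExperiment(mk(g)))
    rd <- rois(expt)
    resp <- responseMatrix(expt)
    mean(resp[, rd$is_target], na.rm = TRUE)
  }
  r1 <- r_of(0.2)
  r2 <- r_of(0.4)
  ## near-linear: the dF/F normalizing mean itself grows slightly with the
  ## evoked tails, so doubling the gain falls just short of doubling the
  ## measured response
  expect_equal(r2 / r1, 2, tolerance = 0.05)
  expect_gt(r1, 0.7 * 0.2)
  expect_lt(r1, 0.2)
})

test_that("shared fluctuations raise pairwise response correlations", {
  corr_of <- function(sf, seed) {
    expt <- addDff(simulateExperiment(quickConfig(
      shared_fluctuation_sd = sf, duration = 400, n_neurons = 16,
      frac_targets = 0.5, seed = seed)))
    rd <- rois(expt)
    resp <- responseMatrix(expt)[, rd$is_target]
    cm <- cor(resp, use = "pairwise.complete.obs")
    mean(cm[upper.tri(cm)])
  }
  ## consistently higher pairwise correlation under shared fluctuations
  d <- vapply(c(21L, 22L, 23L),
              function(s) corr_of(0.5, s) - corr_of(0, s), numeric(1))
  expect_true(all(d > 0))
  expect_gt(mean(d), 0.1)
})

test_that("widefield sessions expose shutter windows and network responses", {
  expt <- addDff(simulateExperiment(quickConfig(
    stim_modality = "widefield", duration = 150, n_neurons = 15,
    frac_targets = 0.4, seed = 27L)))
  trl <- as.data.frame(trials(expt))
  expect_true(all(c("shutter_deploy", "shutter_release") %in% names(trl)))
  expect_true(all(trl$shutter_deploy < trl$onset))
  fov <- colMeans(SummarizedExperiment::assay(expt, "dff"))
  tt <- frameTimes(expt)
  r <- vapply(seq_len(nrow(trl)), function(k)
    widefieldResponse(fov, tt, trl$shutter_deploy[k],
                      trl$shutter_release[k]), numeric(1))
  expect_gt(mean(r, na.rm = TRUE), 0.02)
  ## the mean-field trace decays back below 63% of its peak between trials
  d <- vapply(seq_len(nrow(trl)), function(k)
    decayConstant(fov, tt, trl$shutter_release[k], horizon = 4), numeric(1))
  expect_gt(mean(is.finite(d)), 0.8)
  expect_gt(median(d, na.rm = TRUE), 0.2)
})
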