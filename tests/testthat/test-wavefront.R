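test_that("signed distance to the front follows the penumbra convention", {
  fl <- frontLine(c(0, -100), c(0, 100), ref = c(10, 0))
  expect_equal(distanceToFront(c(0, 37), fl), 0)
  expect_equal(distanceToFront(c(50, 30), fl), 50)
  fl2 <- frontLine(c(0, -100), c(0, 100), ref = c(-10, 0))
  expect_equal(distanceToFront(c(50, 30), fl2), -50)
})

test_that("distance is invariant to point swap and translation along the line", {
  set.seed(7)
  p1 <- c(3, -2); p2 <- c(120, 180); ref <- c(200, -50)
  fl <- frontLine(p1, p2, ref)
  pts <- matrix(rnorm(40, sd = 100), ncol = 2)
  d <- distanceToFront(pts, fl)
  expect_equal(distanceToFront(pts, frontLine(p2, p1, ref)), d,
               tolerance = 1e-9)
  v <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  fl3 <- frontLine(p1 + 31 * v, p2 - 7 * v, ref)
  expect_equal(distanceToFront(pts, fl3), d, tolerance = 1e-9)
  expect_error(frontLine(c(0, 0), c(0, 50), c(1, 0)), "100")
  expect_error(frontLine(c(0, 0), c(0, 150), c(0, 75)), "reference")
})

test_that("proximal/distal classes use the 100 and 200 um cuts", {
  expect_equal(as.character(classifyProximalDistal(c(50, 150, 250, -30))),
               c("proximal", "intermediate", "distal", "intermediate"))
})

test_that("rolling profiles bin values by distance", {
  prof <- rollingProfile(rep(4, 100), runif(100, 0, 300), bin_width = 40)
  expect_true(all(prof$mean[prof$n > 0] == 4))
  ## a single value appears only in bins whose window covers it
  p1 <- rollingProfile(1, 50, bin_width = 40, n_min = 1)
  hit <- p1$n > 0
  expect_true(all(abs(p1$center[hit] - 50) <= 20))
  ## two far-apart groups keep their own means
  p2 <- rollingProfile(c(rep(0, 30), rep(1, 30)),
                       c(rnorm(30, 0, 3), rnorm(30, 300, 3)),
                       bin_width = 40, n_min = 5)
  expect_equal(p2$mean[p2$kept & p2$center < 50], rep(0, sum(p2$kept & p2$center < 50)))
  expect_equal(p2$mean[p2$kept & p2$center > 250],
               rep(1, sum(p2$kept & p2$center > 250)))
  expect_identical(nrow(rollingProfile(numeric(0), numeric(0))), 0L)
})

test_that("trial frame averages are pixel-wise means", {
  st <- array(rep(c(0, 1), each = 4), c(2, 2, 10))  # alternating 0/1 frames
  expect_equal(trialFrameAverage(st, 5, n_frames = 4),
               matrix(0.5, 2, 2))
  expect_equal(trialFrameAverage(st, 3, n_frames = 1), st[, , 3])
  stat <- array(7, c(3, 3, 5))
  expect_equal(trialFrameAverage(stat, 3, n_frames = 4), matrix(7, 3, 3))
  expect_warning(trialFrameAverage(st, 1, n_frames = 8), "clipped")
})

test_that("invasion time marks the start of the rise to the maximum", {
  tt <- seq(0, 20, by = 0.1)
  ramp <- pmin(pmax((tt - 8) / 4, 0), 1)
  expect_equal(invasionTime(ramp, tt, 5, 15), 8, tolerance = 0.2)
  ## two bumps: the rise leading to the larger (second) one wins
  two <- exp(-(tt - 7)^2) + 3 * exp(-(tt - 13)^2 / 2)
  expect_equal(invasionTime(two, tt, 5, 16), 10.2, tolerance = 0.5)
  ## maximum already at onset
  dec <- exp(-(tt - 5) / 2)
  expect_equal(invasionTime(dec, tt, 5, 15), 5)
  expect_true(is.na(invasionTime(rep(1, length(tt)), tt, 5, 15)))
})

test_that("invasion times track ground-truth recruitment on simulation", {
  ## wide field along the propagation axis spreads recruitment over ~4 s;
  ## the analysis window is padded before onset so rise initiations of the
  ## earliest-recruited neurons are resolvable
  expt <- simulateExperiment(simConfig(
    n_neurons = 40, fov = c(1200, 400), duration = 80, injection_time = 20,
    seizure_times = 40, seizure_duration = 10, noise_sd = 0.05, seed = 8L))
  szs <- as.data.frame(seizures(expt))
  gt <- groundTruth(expt)
  rd <- rois(expt)
  raw <- SummarizedExperiment::assay(expt, "fluorescence")
  tt <- frameTimes(expt)
  keep <- which(!is.na(gt$recruitment_time[, 1]))
  inv <- vapply(keep, function(i) {
    tr <- raw[i, ] / rd$f0[i]
    tr[excludedFrames(expt)] <- NA
    tr <- ifelse(is.na(tr), approx(tt[!is.na(tr)], tr[!is.na(tr)], tt)$y, tr)
    invasionTime(tr, tt, szs$onset[1] - 2, szs$offset[1])
  }, numeric(1))
  fit <- lm(inv ~ gt$recruitment_time[keep, 1])
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
  ## initiation is marked at the foot of the rise, shortly before the
  ## ground-truth (half-rise) recruitment time
  resid <- inv - gt$recruitment_time[keep, 1]
  expect_lt(mean(resid), 0)
  expect_gt(mean(resid), -0.8)
})

test_that("annotated front displacement matches ground truth at each trial", {
  expt <- quickSeizureExperiment(seed = 12L)
  fls <- as.data.frame(frontLines(expt))
  trl <- as.data.frame(trials(expt))
  szs <- as.data.frame(seizures(expt))
  gt <- groundTruth(expt)
  rd <- rois(expt)
  cfg <- S4Vectors::metadata(expt)$config
  expect_gt(nrow(fls), 0)
  for (r in seq_len(nrow(fls))) {
    k <- match(fls$trial_id[r], trl$trial_id)
    fl <- frontLine(c(fls$x1[r], fls$y1[r]), c(fls$x2[r], fls$y2[r]),
                    c(fls$ref_x[r], fls$ref_y[r]))
    d <- distanceToFront(cbind(rd$x, rd$y), fl)
    truth <- gt$proj_coord -
      gt$speed * (trl$onset[k] - szs$onset[fls$seizure_id[r]])
    expect_equal(d, truth, tolerance = gt$speed / frameRate(expt))
  }
})
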