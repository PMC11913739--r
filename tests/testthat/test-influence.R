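test_that("influence metric reproduces the hand-derived 2x2 oracle", {
  out <- influenceMetric(rbind(c(1, 3), c(2, 6)))
  expect_equal(out$predicted, c(2, 4), tolerance = 1e-12)
  expect_equal(out$difference, rbind(c(-1, 1), c(-2, 2)), tolerance = 1e-12)
  expect_equal(out$influence,
               rbind(c(-1, 1) / sd(c(-1, -2)), c(-2, 2) / sd(c(1, 2))),
               tolerance = 1e-12)
  expect_equal(out$influence[1, ], c(-sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(out$influence[2, ], c(-2 * sqrt(2), 2 * sqrt(2)),
               tolerance = 1e-12)
})

test_that("influence is invariant to shared per-trial offsets", {
  set.seed(8)
  r <- matrix(rnorm(60), 10, 6)
  base <- influenceMetric(r)
  shifted <- r + rnorm(10)  # a different common offset on every trial
  out <- influenceMetric(shifted)
  expect_equal(out$difference, base$difference, tolerance = 1e-12)
  expect_equal(out$influence, base$influence, tolerance = 1e-12)
})

test_that("degenerate response matrices give undefined influence", {
  r <- matrix(5, 4, 3)
  out <- influenceMetric(r)
  expect_true(all(out$difference == 0))
  expect_true(all(is.na(out$influence)))
  expect_error(influenceMetric(matrix(1, 1, 3)), "two trials")
})

test_that("artificial trials sit at inter-trial midpoints", {
  sham <- artificialTrials(data.frame(onset = c(0, 10), offset = c(1, 11)))
  expect_equal(sham$onset, 5)
  expect_equal(sham$offset, 6)
  expect_identical(sham$modality, "artificial")
  expect_identical(nrow(artificialTrials(data.frame(onset = 0, offset = 1))),
                   0L)
  reg <- artificialTrials(data.frame(onset = seq(0, 20, by = 5),
                                     offset = seq(0, 20, by = 5) + 0.3))
  expect_equal(reg$onset, seq(2.5, 17.5, by = 5))
  ## too-short gaps emit no sham
  tight <- artificialTrials(data.frame(onset = c(0, 2.1), offset = c(1, 3.1)))
  expect_identical(nrow(tight), 0L)
})

test_that("influence-distance attribution respects the 400 um radius", {
  infl <- matrix(c(1, 2, 3), 3, 1)
  prof <- influenceVsDistance(infl, cbind(100, 120), cbind(100, 0))
  expect_equal(prof$n_pairs[prof$lo == 80], 1L)
  expect_equal(prof$mean[prof$lo == 80], 2)
  expect_true(all(prof$n_pairs[prof$lo != 80] == 0))
  far <- influenceVsDistance(infl, cbind(100, 450), cbind(100, 0))
  expect_true(all(far$n_pairs == 0))
})

test_that("simulated short-range coupling shows up only in near bins", {
  ## positive coupling within 25 um only; profile positive there, ~0 beyond
  cfg <- influenceBenchConfig(seed = 31L, coupling_weight = 0.15)
  cfg@coupling_kernel <- function(d, w) ifelse(d <= 25, w, 0)
  expt <- addDff(simulateExperiment(cfg))
  trl <- as.data.frame(trials(expt))
  rd <- rois(expt)
  it <- which(trl$state == "interictal")
  nt <- selectNontargets(rd)
  resp <- responseMatrix(expt, trials = trl[it, ])
  im <- influenceMetric(resp[, match(nt$roi_id, rd$roi_id), drop = FALSE])
  prof <- influenceVsDistance(im$influence, cbind(nt$x, nt$y),
                              cbind(rd$x[rd$is_target], rd$y[rd$is_target]),
                              breaks = c(0, 25, 200, 400))
  expect_gt(prof$mean[1], 0)
  expect_lt(abs(prof$mean[2]), 3 * prof$sem[2])
  expect_lt(abs(prof$mean[3]), 3 * prof$sem[3])
})

test_that("artificial trials on seizure-free data give null influence", {
  cfg <- influenceBenchConfig(seed = 32L, coupling_weight = 0.1)
  expt <- addDff(simulateExperiment(cfg))
  trl <- as.data.frame(trials(expt))
  sham <- artificialTrials(trl[trl$state == "interictal", ])
  rd <- rois(expt)
  nt <- selectNontargets(rd)
  resp <- responseMatrix(expt, trials = sham)
  im <- influenceMetric(resp[, match(nt$roi_id, rd$roi_id), drop = FALSE])
  m <- colMeans(im$influence, na.rm = TRUE)
  expect_lt(abs(mean(m)), 2 * sd(m) / sqrt(length(m)) + 0.02)
})

test_that("target/non-target totals are z-scored with their correlation", {
  t1 <- matrix(c(1, 2, 3), 3, 1)
  out <- targetVsNontargetTotals(t1, 2 * t1)
  expect_equal(out$totals$target_total_z, c(-1, 0, 1))
  expect_equal(out$totals$nontarget_total_z, c(-1, 0, 1))
  expect_equal(out$correlation, 1)
  same <- targetVsNontargetTotals(matrix(1, 3, 2), matrix(2, 3, 2))
  expect_true(all(is.na(same$totals$target_total_z)))
  expect_true(is.na(same$correlation))
})
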