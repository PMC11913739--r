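test_that("simConfig validates its invariants", {
  expect_s4_class(simConfig(), "SimConfig")
  expect_error(simConfig(frac_targets = 1.2), "frac_targets")
  expect_error(simConfig(frame_rate = 0), "frame_rate")
  expect_error(simConfig(wavefront_speed = -1), "wavefront_speed")
  expect_error(simConfig(postictal_suppression = 0), "postictal")
  ## overlapping scheduled seizures are rejected
  expect_error(simConfig(duration = 200, seizure_times = c(100, 110),
                         seizure_duration = 20), "overlap")
  ## direction is normalized by the constructor
  cfg <- simConfig(wavefront_direction = c(3, 4))
  expect_equal(sum(cfg@wavefront_direction^2), 1)
})

test_that("default gain and coupling kernels follow the stated bands", {
  expect_equal(defaultFrontGain(c(-50, 50, 150, 250)), c(0.1, 0.3, 1.0, 1.5))
  expect_equal(defaultCouplingKernel(c(10, 100, 300), w = 0.2),
               c(0.2, -0.2, 0))
})

test_that("identical seeds give bit-identical experiments", {
  cfg <- quickConfig(seizure_times = 40, duration = 70, seizure_duration = 8,
                     trigger_prob = 0.3, seed = 5L)
  e1 <- simulateExperiment(cfg)
  e2 <- simulateExperiment(cfg)
  expect_identical(SummarizedExperiment::assay(e1, "fluorescence"),
                   SummarizedExperiment::assay(e2, "fluorescence"))
  expect_identical(as.data.frame(trials(e1)), as.data.frame(trials(e2)))
  expect_identical(lfpProxy(e1)$signal, lfpProxy(e2)$signal)
})

test_that("zero-noise, zero-rate, seizure-free non-targets only show coupling", {
  cfg <- quickConfig(noise_sd = 0, transient_rate = 0, stim_global_amp = 0,
                     shared_fluctuation_sd = 0, coupling_weight = 0.2,
                     n_neurons = 20, frac_targets = 0.15,
                     fov = c(1200, 1200), seed = 9L)
  expt <- simulateExperiment(cfg)
  rd <- rois(expt)
  raw <- SummarizedExperiment::assay(expt, "fluorescence")
  sig <- raw / rd$f0 - 1
  sig[, excludedFrames(expt)] <- 0   # artifact frames carry the stim artifact
  nt <- which(!rd$is_target)
  tg <- which(rd$is_target)
  D <- sqrt(outer(rd$x[tg], rd$x[nt], "-")^2 +
            outer(rd$y[tg], rd$y[nt], "-")^2)
  coupled <- nt[colSums(D <= 200) > 0]
  uncoupled <- setdiff(nt, coupled)
  expect_true(length(uncoupled) > 0)
  expect_true(all(abs(sig[uncoupled, ]) < 1e-12))
  expect_true(any(abs(sig[coupled, ]) > 1e-6))
})

test_that("ground-truth recruitment time is onset + distance / speed", {
  ## a neuron 300 um along the propagation axis recruits 3 s after onset
  ## at 100 um/s (closed form d / v)
  cfg <- simConfig(n_neurons = 5, fov = c(500, 500), duration = 60,
                   injection_time = 10, seizure_times = 30,
                   seizure_duration = 10, wavefront_speed = 100,
                   wavefront_direction = c(1, 0), seed = 2L)
  expt <- simulateExperiment(cfg)
  rd <- rois(expt)
  gt <- groundTruth(expt)
  expect_equal(gt$recruitment_time[, 1], 30 + rd$x / 100,
               tolerance = 1e-12)
})

test_that("empirical recruitment order is monotone in the projected coordinate", {
  expt <- addDff(quickSeizureExperiment(seed = 3L, n_neurons = 30,
                                        noise_sd = 0.02))
  szs <- as.data.frame(seizures(expt))
  tt <- frameTimes(expt)
  dff <- SummarizedExperiment::assay(expt, "dff")
  excl <- excludedFrames(expt)
  delays <- vapply(seq_len(nrow(dff)), function(i) {
    al <- alignToSeizure(dff[i, ], tt, szs$onset[1], excluded = excl)
    recruitmentDelay(al, tt, szs$onset[1], szs$offset[1], frac = 0.65,
                     excluded = excl)
  }, numeric(1))
  proj <- groundTruth(expt)$proj_coord
  expect_gt(cor(delays, proj, method = "spearman"), 0.99)
})

test_that("unrecruited neurons stay at baseline during a seizure", {
  ## front at 300 um/s crosses only part of a large field before offset
  cfg <- simConfig(n_neurons = 40, fov = c(2000, 400), duration = 80,
                   injection_time = 20, seizure_times = 40,
                   seizure_duration = 3, noise_sd = 0.05, seed = 4L)
  expt <- simulateExperiment(cfg)
  gt <- groundTruth(expt)
  unrec <- which(is.na(gt$recruitment_time[, 1]))
  expect_true(length(unrec) > 0)
  raw <- SummarizedExperiment::assay(expt, "fluorescence")
  rd <- rois(expt)
  tt <- frameTimes(expt)
  insz <- tt >= 40 & tt <= 43 & !excludedFrames(expt)
  presz <- tt < 20 & !excludedFrames(expt)
  ## population average: single neurons fluctuate with their own sparse
  ## spontaneous transients, but unrecruited tissue shows no ictal elevation
  m_in <- mean(rowMeans(raw[unrec, insz]) / rd$f0[unrec])
  m_pre <- mean(rowMeans(raw[unrec, presz]) / rd$f0[unrec])
  expect_lt(abs(m_in - m_pre), 0.1)
})

test_that("the LFP proxy oscillates strongly only within seizures", {
  expt <- quickSeizureExperiment(seed = 6L)
  lfp <- lfpProxy(expt)
  szs <- as.data.frame(seizures(expt))
  inside <- lfp$time >= szs$onset[1] & lfp$time <= szs$offset[1]
  expect_gt(sd(lfp$signal[inside]), 3 * sd(lfp$signal[!inside]))
})

test_that("stimulation-triggered seizures are recorded with their trial", {
  expt <- simulateExperiment(triggeredSeizureConfig(seed = 1L))
  szs <- as.data.frame(seizures(expt))
  gt <- groundTruth(expt)
  expect_true(all(!is.na(szs$triggered_by)))
  expect_gte(nrow(szs), 10)
  ## triggered onsets sit close to their trial's onset
  trl <- as.data.frame(trials(expt))
  d <- abs(szs$onset - trl$onset[match(szs$triggered_by, trl$trial_id)])
  expect_true(all(d < 1))
})

test_that("frontLineAt reproduces the line geometry", {
  cfg <- simConfig(fov = c(400, 400), wavefront_speed = 100,
                   wavefront_direction = c(1, 0))
  sz <- data.frame(onset = 10, offset = 20)
  f0 <- frontLineAt(sz, t = 10, cfg)
  expect_equal(f0@p1[1], 0)            # onset line enters at the field edge
  expect_equal(f0@p1[1], f0@p2[1])     # vertical for direction (1, 0)
  f1 <- frontLineAt(sz, t = 11, cfg)
  expect_equal(f1@p1[1], 100)          # displaced speed * (t - onset)
  expect_gt(f1@ref[1], f1@p1[1])       # reference on the unrecruited side
  expect_error(frontLineAt(sz, t = 25, cfg), "within the seizure")
})
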