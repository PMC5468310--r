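## synthetic trace helper
mkTrace <- function(t, v, section = "soma") {
  new("Trace", times = t, v = matrix(v, ncol = 1),
      sites = data.frame(section = section, arc = 0.5, comp = 1L))
}

test_that("spike detection counts threshold crossings with refractoriness", {
  t <- seq(0, 100, by = 0.1)
  expect_equal(nSpikes(detectSpikes(mkTrace(t, rep(-65, length(t))))), 0L)
  ## five suprathreshold cycles -> five spikes
  osc <- mkTrace(t, -30 + 40 * sin(2 * pi * t / 20))
  expect_equal(nSpikes(detectSpikes(osc, threshold = 0)), 5L)
  ## crossings exactly 1 ms apart with a 2 ms refractory: every second
  ## crossing suppressed
  fast <- mkTrace(t, -30 + 40 * ((t %% 1) >= 0.5))
  all_cross <- detectSpikes(fast, threshold = 0, refractory = 0)
  expect_equal(nSpikes(all_cross), 100L)
  st <- detectSpikes(fast, threshold = 0, refractory = 1.5)
  expect_equal(nSpikes(st), 50L)
  expect_true(all(diff(st@spike_times) >= 1.5))
  expect_error(detectSpikes(osc, site = "dend1"), "unknown site")
})

test_that("firing rate is count over window length", {
  sp <- new("SpikeTrain", spike_times = c(100, 300, 500, 700, 900),
            detection_threshold = 0, refractory = 2)
  expect_equal(firingRate(sp, c(0, 1000)), 5)
  expect_equal(firingRate(sp, c(2000, 3000)), 0)
  none <- new("SpikeTrain", spike_times = numeric(0),
              detection_threshold = 0, refractory = 2)
  expect_equal(firingRate(none, c(0, 1000)), 0)
  expect_error(firingRate(sp, c(500, 500)), "window")
})

test_that("a passive membrane has no EF firing threshold", {
  res <- findEFThreshold(straightFiber(100, 2), fix_pas, polarity = "+",
                         e_max = 300, coarse_step = 150,
                         config = solverConfig(duration = 300))
  expect_false(res@found)
  expect_true(is.na(res@e_threshold))
  expect_true(all(res@search_log$n_spikes == 0))
})

test_that("threshold search brackets are sound and reproducible", {
  res <- findEFThreshold(fix_sys, polarity = "+", e_max = 1000,
                         resolution = 5, coarse_step = 100,
                         config = fix_cfg, init = fix_init)
  expect_true(res@found)
  expect_lte(abs(res@bracket[2]) - abs(res@bracket[1]), 5)
  ## re-simulate both bracket ends
  n_lo <- cableEF:::.spikeCount(fix_sys, fix_init, res@bracket[1], fix_cfg,
                                NULL, 100, 600)
  n_hi <- cableEF:::.spikeCount(fix_sys, fix_init, res@bracket[2], fix_cfg,
                                NULL, 100, 600)
  expect_equal(n_lo, 0L)
  expect_gte(n_hi, 1L)
  res2 <- findEFThreshold(fix_sys, polarity = "+", e_max = 1000,
                          resolution = 5, coarse_step = 100,
                          config = fix_cfg, init = fix_init)
  expect_identical(res@e_threshold, res2@e_threshold)
  expect_identical(res@search_log, res2@search_log)
})

test_that("a zero-amplitude EPSC reproduces the plain threshold exactly", {
  plain <- findEFThreshold(fix_sys, polarity = "+", e_max = 600,
                           resolution = 10, coarse_step = 200,
                           config = fix_cfg, init = fix_init)
  with0 <- thresholdWithEPSC(fix_sys, epsc = epscStimulus(amplitude = 0),
                             polarity = "+", e_max = 600, resolution = 10,
                             coarse_step = 200, config = fix_cfg,
                             init = fix_init)
  expect_identical(plain@e_threshold, with0@e_threshold)
})

test_that("a suprathreshold EPSC violates the protocol precondition", {
  expect_error(
    thresholdWithEPSC(fix_sys, epsc = epscStimulus(amplitude = 0.03),
                      polarity = "+", config = fix_cfg, init = fix_init),
    "subthreshold")
})

test_that("a subthreshold EPSC lowers the EF firing threshold", {
  plain <- findEFThreshold(fix_sys, polarity = "+", e_max = 800,
                           resolution = 2, coarse_step = 100,
                           config = fix_cfg, init = fix_init)
  with_epsc <- thresholdWithEPSC(fix_sys,
                                 epsc = epscStimulus(amplitude = 0.01),
                                 polarity = "+", e_max = 800, resolution = 2,
                                 coarse_step = 100, config = fix_cfg,
                                 init = fix_init)
  expect_true(with_epsc@found)
  expect_lt(with_epsc@e_threshold, plain@e_threshold)
})

test_that("AP diagnostics report axonal dominance and the first site", {
  tr <- simulate(fix_sys, field = fieldStimulus(450), config = fix_cfg,
                 init = fix_init, record = "all")
  d <- apSiteDiagnostics(tr)
  pk <- d$site_peaks
  expect_gt(max(pk$peak[pk$section == "axon"]),
            pk$peak[pk$section == "soma"])
  expect_equal(d$initiation$section, "axon")
  ## degenerate single-site trace: that site is trivially the initiation site
  t <- seq(0, 50, by = 0.1)
  single <- mkTrace(t, -65 + 80 * exp(-((t - 25) / 2)^2))
  ds <- apSiteDiagnostics(single, threshold = 0)
  expect_equal(ds$initiation$section, "soma")
  flat <- mkTrace(t, rep(-65, length(t)))
  expect_error(apSiteDiagnostics(flat), "no spike")
})

test_that("somatic polarization is linear in the field", {
  ## passive membrane: the system is exactly linear
  pol_pas <- polarizationVsE(fix_tree, fix_pas, e_grid = c(-40, -20, 20, 40),
                             config = solverConfig(duration = 300))
  expect_lt(pol_pas$residual_max, 1e-6)
  ## full model on +/-50 mV/mm: residual below 5% of the largest deflection
  pol_act <- polarizationVsE(fix_sys, e_grid = c(-50, -25, 25, 50),
                             config = fix_cfg)
  expect_lt(pol_act$residual_max, 0.05 * max(abs(pol_act$table$soma_delta_v)))
  ## doubling dendritic lengths changes the slope
  long <- buildArtificialNeuron(artificialNeuronParams(
    proximal_dend_length = 16, distal_dend_length = 4))
  pol_long <- polarizationVsE(long, fix_pas, e_grid = c(-40, -20, 20, 40),
                              config = solverConfig(duration = 300))
  pol_base <- polarizationVsE(fix_tree, fix_pas, e_grid = c(-40, -20, 20, 40),
                              config = solverConfig(duration = 300))
  expect_gt(abs(pol_long$slope - pol_base$slope), 1e-4)
})

test_that("f-E curves vanish below threshold and reproduce exactly", {
  fe <- fECurve(fix_sys, e_grid = c(-200, -100, 100, 200), config = fix_cfg,
                init = fix_init)
  expect_true(all(fe@table$f == 0))
  fe2 <- fECurve(fix_sys, e_grid = c(380, 420, 460), config = fix_cfg,
                 init = fix_init)
  fe3 <- fECurve(fix_sys, e_grid = c(380, 420, 460), config = fix_cfg,
                 init = fix_init)
  expect_identical(fe2@table, fe3@table)
  expect_true(any(fe2@table$f > 0))
})

test_that("sweeps cover every supported parameter and reject unknown ones", {
  expect_error(sweepThreshold(parameter = "soma_radius", values = 1:2),
               "unknown parameter")
  sw <- sweepThreshold(parameter = "axon_length", values = c(40, 80),
                       polarity = "+", biophysics = fix_bio,
                       e_max = 1200, resolution = 10, coarse_step = 200,
                       config = fix_cfg)
  expect_s4_class(sw, "SweepResult")
  expect_equal(length(sw@thresholds), 2L)
  expect_true(all(is.finite(sw@thresholds)))
  ## longer axon -> lower threshold
  expect_lt(sw@thresholds[2], sw@thresholds[1])
  df <- sweepToDataFrame(sw)
  expect_equal(names(df), c("parameter", "value", "threshold"))
})
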