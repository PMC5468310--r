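test_that("extracellular potentials follow the uniform-field geometry", {
  sys <- fix_sys
  expect_equal(extracellularPotentials(sys, 0), rep(0, nrow(sys@comp)))
  ## two centers 100 um apart along y at E = 50 mV/mm differ by 5 mV
  fib <- compartmentalize(straightFiber(300, 2), fix_pas, max_dx = 100)
  v <- extracellularPotentials(fib, 50)
  dy <- diff(fib@comp$y)
  expect_equal(abs(dy)[1], 100)
  expect_equal(diff(v), 50 * dy / 1000, tolerance = 1e-12)
  expect_equal(abs(diff(v))[1], 5, tolerance = 1e-9)
  ## cathode reference plane: all stored potentials are >= 0 either polarity
  expect_true(all(extracellularPotentials(sys, 120) >= 0))
  expect_true(all(extracellularPotentials(sys, -120) >= 0))
  ## an element perpendicular to the field axis sees no difference
  horiz <- applyBend(straightFiber(300, 2), "soma", 90)
  hsys <- compartmentalize(horiz, fix_pas, max_dx = 100)
  expect_lt(max(abs(diff(extracellularPotentials(hsys, 50)))), 1e-12)
})

test_that("axial conductance follows the half-compartment series law", {
  pas <- passiveParams()
  fib <- compartmentalize(straightFiber(100, 2), fix_pas, max_dx = 20)
  dx <- fib@comp$len[1]
  g_expect <- (pi * 2^2 / 4) / (pas@ra * 1e4 * dx) * 1e6 # uS
  expect_equal(axialConductance(fib, 1, 2), g_expect, tolerance = 1e-9)
  ## d -> 2d quadruples, dx -> 2dx halves
  fib2 <- compartmentalize(straightFiber(100, 4), fix_pas, max_dx = 20)
  expect_equal(axialConductance(fib2, 1, 2), 4 * g_expect, tolerance = 1e-9)
  fib3 <- compartmentalize(straightFiber(200, 2), fix_pas, max_dx = 40)
  expect_equal(axialConductance(fib3, 1, 2), g_expect / 2, tolerance = 1e-9)
  expect_error(axialConductance(fib, 1, 3), "not adjacent")
})

test_that("junction conductance equals the two-resistor hand computation", {
  ## soma (10 um long, 10 um diam, 1 compartment) joined to the axon's first
  ## compartment (10 um long, 2 um diam): R = R1/2 + R2/2
  pas <- passiveParams()
  sys <- fix_sys
  comp <- sys@comp
  ax1 <- which(comp$section == "axon")[1]
  soma <- which(comp$section == "soma")
  r_half <- function(len, d) pas@ra * 1e4 * (len / 2) / (pi * d^2 / 4)
  r_hand <- r_half(comp$len[soma], 10) + r_half(comp$len[ax1], 2)
  expect_equal(axialConductance(sys, soma, ax1), 1e6 / r_hand,
               tolerance = 1e-9)
})

test_that("the implicit step matches the analytic 2-compartment solution", {
  ## two 100 um x 1 um cylinders (soma + axon, one compartment each). The
  ## per-step (local) error of the compiled implicit step is measured by
  ## starting each step from the exact matrix-exponential state of the
  ## corresponding 2-ODE linear system and advancing one step.
  s <- data.frame(id = c("soma", "axon"), kind = c("soma", "axon"),
                  x0 = 0, y0 = c(0, 0), x1 = 0, y1 = c(100, -100),
                  diam = 1, parent = c(NA, "soma"),
                  attach_end = c(NA, "proximal"), stringsAsFactors = FALSE)
  tree2 <- new("MorphologyTree", sections = s, metadata = list())
  sys <- compartmentalize(tree2, fix_pas, max_dx = 100)
  expect_equal(nrow(sys@comp), 2L)
  cm <- sys@cm; gl <- sys@gleak; gax <- sys@comp$g_axial[2]
  v0 <- c(-80, -50)
  dt <- 2e-5; nsteps <- 100L
  states <- analytic2comp(cm, gl, -65, gax, v0, t = (0:nsteps) * dt)
  err <- vapply(seq_len(nsteps), function(k) {
    one <- cableEF:::.rawSimulate(sys, v0 = states[, k], gates0 = matrix(0, 2, 0),
                                  e_amp = 0, e_on = 0, e_off = 1, inj = NULL,
                                  dt = dt, duration = dt,
                                  record_idx = 1:2, record_stride = 1L)
    max(abs(one$v_final - states[, k + 1L]))
  }, numeric(1))
  expect_lt(max(err), 1e-6)
})

test_that("the compiled stepper matches the dense R reference stepper", {
  cfg <- solverConfig(duration = 20, use_tables = FALSE)
  small <- buildArtificialNeuron(artificialNeuronParams(n_dendrites = 3L))
  for (bio in list(fix_pas, fix_bio)) {
    sys <- compartmentalize(small, bio, max_dx = 10)
    init <- initSteadyState(sys, cfg)
    nsteps <- 800L
    ## perturbed start + field + injection exercises every term
    v0 <- init$v + seq(-5, 5, length.out = nrow(sys@comp))
    inj <- list(comp = nrow(sys@comp), amp = 0.005, on = 5, off = 15)
    ref <- refSimulate(sys, v0, init$gates, e_amp = 80, e_on = 2, e_off = 18,
                       inj = inj, dt = 0.025, nsteps = nsteps)
    out <- cableEF:::.rawSimulate(sys, v0 = v0, gates0 = init$gates,
                                  e_amp = 80, e_on = 2, e_off = 18,
                                  inj = inj, dt = 0.025,
                                  duration = nsteps * 0.025,
                                  record_idx = seq_len(nrow(sys@comp)),
                                  record_stride = 1L, use_tables = FALSE)
    expect_lt(max(abs(out$v - ref$v)), 1e-6)
  }
})

test_that("passive responses are linear in E and negate under reversal", {
  fib_tree <- straightFiber(600, 1)
  sys <- compartmentalize(fib_tree, fix_pas, max_dx = 10)
  cfg <- solverConfig(duration = 200)
  tr1 <- simulate(sys, field = fieldStimulus(20, onset = 20, offset = 180),
                  config = cfg, record = "all")
  tr2 <- simulate(sys, field = fieldStimulus(40, onset = 20, offset = 180),
                  config = cfg, record = "all")
  trn <- simulate(sys, field = fieldStimulus(-20, onset = 20, offset = 180),
                  config = cfg, record = "all")
  d1 <- tr1@v - fix_pas@passive@e_leak
  d2 <- tr2@v - fix_pas@passive@e_leak
  dn <- trn@v - fix_pas@passive@e_leak
  scale <- max(abs(d2))
  expect_lt(max(abs(d2 - 2 * d1)) / scale, 0.005)
  expect_lt(max(abs(dn + d1)) / scale, 0.005)
})

test_that("the somatic trace self-converges as dt is halved", {
  sys <- compartmentalize(straightFiber(600, 1), fix_pas, max_dx = 10)
  run <- function(dt) {
    cfg <- solverConfig(dt = dt, duration = 100,
                        record_stride = round(0.1 / dt))
    simulate(sys, field = fieldStimulus(30, onset = 10, offset = 90),
             config = cfg, record = "all")@v
  }
  v1 <- run(0.05)
  v2 <- run(0.025)
  expect_lt(max(abs(v1 - v2)), 0.1)
})

test_that("junction currents balance at every step", {
  cfg <- solverConfig(duration = 300)
  tr <- simulate(fix_sys, field = fieldStimulus(500), config = cfg,
                 init = fix_init, track_residual = TRUE)
  expect_gt(nSpikes(detectSpikes(tr)), 0) # exercised through spikes
  expect_lt(tr@info$max_residual, 1e-9)
})

test_that("dynamics are invariant to a constant extracellular offset", {
  sys <- fix_sys
  base <- cableEF:::.rawSimulate(sys, v0 = fix_init$v, gates0 = fix_init$gates,
                                 e_amp = 300, e_on = 50, e_off = 250,
                                 inj = NULL, dt = 0.025, duration = 300,
                                 record_idx = 1L, record_stride = 10L)
  off <- cableEF:::.rawSimulate(sys, v0 = fix_init$v, gates0 = fix_init$gates,
                                e_amp = 300, e_on = 50, e_off = 250,
                                inj = NULL, dt = 0.025, duration = 300,
                                record_idx = 1L, record_stride = 10L,
                                vext_offset = 7.5)
  expect_lt(max(abs(base$v - off$v)), 1e-9)
})

test_that("steady polarization of a sealed fiber matches the closed form", {
  pas <- passiveParams()
  lam <- lambdaUm(pas, 1)
  L <- 3 * lam
  sys <- compartmentalize(straightFiber(L, 1), passiveBiophysics(pas),
                          max_dx = lam / 50)
  pol <- steadyStatePolarization(sys, E = 10, config = solverConfig(),
                                 settle = 400)
  expected <- fiberPolarization(sys@comp$y, L, lam, 10)
  expect_lt(max(abs(pol$delta_v - expected)) / max(abs(expected)), 0.01)
  ## midpoint unpolarized; reversal negates within 0.5%
  mid <- which.min(abs(sys@comp$y - L / 2))
  expect_lt(abs(pol$delta_v[mid]), 0.01 * max(abs(expected)))
  pol_n <- steadyStatePolarization(sys, E = -10, config = solverConfig(),
                                   settle = 400)
  expect_lt(max(abs(pol_n$delta_v + pol$delta_v)) / max(abs(pol$delta_v)),
            0.005)
})

test_that("polarization profiles converge spatially", {
  ## halving the compartment length changes section-midpoint polarization
  ## by < 1% sup-norm (midpoint compartments exist at both resolutions)
  prof <- function(max_dx) {
    sys <- compartmentalize(fix_tree, fix_pas, max_dx = max_dx)
    pol <- steadyStatePolarization(sys, E = 50, config = solverConfig(),
                                   settle = 300)
    mids <- pol[abs(pol$arc - 0.5) < 1e-9, ]
    mids$delta_v[order(mids$section)]
  }
  p10 <- prof(10)
  p5 <- prof(5)
  expect_lt(max(abs(p10 - p5)) / max(abs(p5)), 0.01)
})

test_that("a suprathreshold field is rejected during polarization", {
  expect_error(
    steadyStatePolarization(fix_sys, E = 600, config = fix_cfg,
                            init = fix_init),
    "suprathreshold")
})

test_that("divergence is reported with time and site", {
  ## an absurd injected current blows the voltage past the guard
  sys <- compartmentalize(straightFiber(20, 1), fix_pas, max_dx = 10)
  expect_error(
    simulate(sys, injections = new("EPSCStimulus", target_section = "soma",
                                   arc_position = 0.5, amplitude = 1e6,
                                   onset = 1, duration = 50),
             config = solverConfig(duration = 20)),
    "diverged.*ms")
})
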