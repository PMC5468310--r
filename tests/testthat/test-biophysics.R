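test_that("density rules evaluate to the documented values", {
  rules <- defaultDensityRules()
  expect_equal(densityAt(rules$ka, 0, "soma"), 250)
  expect_equal(densityAt(rules$ka, 100, "dend_distal"), 500)
  expect_equal(densityAt(rules$h, 100, "dend_distal"), 2.0)
  expect_equal(densityAt(rules$h, 0, "soma"), 0.5)
  ## flat channels ignore distance; sloped channels are flat off-dendrite
  expect_equal(densityAt(rules$na, c(0, 50, 300), rep("axon", 3)), rep(200, 3))
  expect_equal(densityAt(rules$kdr, 250, "dend_distal"), 100)
  expect_equal(densityAt(rules$ka, 200, "axon"), 250)
  expect_error(densityAt(rules$ka, -1), "distance")
})

test_that("density rules are non-negative and piecewise linear in distance", {
  d <- seq(0, 600, by = 10)
  for (rule in defaultDensityRules()) {
    v <- densityAt(rule, d, rep("dend_distal", length(d)))
    expect_true(all(v >= 0))
    ## linear: second differences vanish
    expect_equal(max(abs(diff(diff(v)))), 0, tolerance = 1e-9)
  }
})

test_that("the unit conversion satisfies 1 pS/um^2 == 0.1 mS/cm^2", {
  expect_identical(psum2_to_mscm2(1), 0.1)
  expect_equal(psum2_to_mscm2(250), 25)
})

test_that("the default kinetic scheme is well formed over the working range", {
  kin <- defaultKineticScheme()
  expect_setequal(names(kin@channels), c("na", "kdr", "ka", "h"))
  expect_true(all(c("na", "k", "h") %in% names(kin@reversals)))
  expect_match(kin@hash, "^[0-9a-f]{32}$")
  v <- seq(-120, 60, by = 0.5)
  for (ch in kin@channels) {
    for (g in ch$gates) {
      inf <- gateInf(g, v)
      tau <- gateTau(g, v)
      expect_true(all(inf >= 0 & inf <= 1))
      expect_true(all(tau > 0))
    }
  }
})

test_that("malformed kinetic scheme files are rejected", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "x", version = "1",
                        reversals = list(k = -90)), f)
  expect_error(readKineticScheme(f), "channels")
  spec <- yaml::read_yaml(system.file("extdata", "kinetics", "ca1_default.yaml",
                                      package = "cableEF"))
  spec$channels$na$reversal <- "unobtainium"
  yaml::write_yaml(spec, f)
  expect_error(readKineticScheme(f), "na")
})

test_that("membrane current vanishes at the appropriate reversals", {
  kin <- defaultKineticScheme()
  pas <- passiveParams()
  dens <- c(na = 200, kdr = 100, ka = 250, h = 0.5)
  zero_gates <- list(na = c(m = 0, h = 0), kdr = c(n = 0),
                     ka = c(a = 0, b = 0), h = c(l = 0))
  ## all gates closed at the leak reversal: every term vanishes
  expect_equal(membraneCurrent(pas@e_leak, zero_gates, dens, kin, pas), 0)
  ## only Na conducting, V at E_Na: zero driving force
  na_open <- list(na = c(m = 1, h = 1), kdr = c(n = 0),
                  ka = c(a = 0, b = 0), h = c(l = 0))
  ena <- kin@reversals[["na"]]
  i_na <- membraneCurrent(ena, na_open, dens, kin, pas)
  expect_equal(i_na, (ena - pas@e_leak) / pas@rm) # leak term only
})

test_that("membrane current is linear in the conductance densities", {
  kin <- defaultKineticScheme()
  pas <- passiveParams()
  dens <- c(na = 200, kdr = 100, ka = 250, h = 0.5)
  gates <- list(na = c(m = 0.3, h = 0.6), kdr = c(n = 0.4),
                ka = c(a = 0.2, b = 0.7), h = c(l = 0.1))
  v <- -40
  i1 <- membraneCurrent(v, gates, dens, kin, pas)
  i2 <- membraneCurrent(v, gates, 2 * dens, kin, pas)
  leak <- (v - pas@e_leak) / pas@rm
  expect_equal(i2 - leak, 2 * (i1 - leak), tolerance = 1e-12)
})

test_that("passive initialization is exactly the leak reversal", {
  sys <- compartmentalize(fix_tree, fix_pas)
  init <- initSteadyState(sys)
  expect_identical(init$v, rep(fix_pas@passive@e_leak, nrow(sys@comp)))
  expect_identical(init$drift, 0)
})

test_that("full-model initialization is stationary and reproducible", {
  ## drift bound: 100 ms with no stimulus moves the soma by < 0.1 mV
  tr <- simulate(fix_sys, config = solverConfig(duration = 100),
                 init = fix_init)
  expect_lt(max(tr@v) - min(tr@v), 0.1)
  init2 <- initSteadyState(fix_sys, fix_cfg)
  expect_identical(fix_init$v, init2$v)
  expect_identical(fix_init$gates, init2$gates)
  ## gating variables sit at their steady state for the local voltage
  kin <- fix_sys@kin
  for (g in seq_along(kin$gate_channel)) {
    inf <- 1 / (1 + exp((kin$vhalf[g] - fix_init$v) / kin$k[g]))
    expect_equal(fix_init$gates[, g], inf, tolerance = 1e-4)
  }
})
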