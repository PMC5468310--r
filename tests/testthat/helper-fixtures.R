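## Shared fixtures, built in code at load time. Heavyweight objects (the
## default compartmental system and its resting state) are built once and
## reused across test files.

## a bare cylindrical fiber along +y (soma-only tree), for closed-form cable
## checks
straightFiber <- function(length_um, diam_um) {
  s <- data.frame(id = "soma", kind = "soma", x0 = 0, y0 = 0,
                  x1 = 0, y1 = length_um, diam = diam_um,
                  parent = NA_character_, attach_end = NA_character_,
                  stringsAsFactors = FALSE)
  new("MorphologyTree", sections = s, metadata = list())
}

## cable length constant in um (Rm kOhm cm^2, d um, Ra Ohm cm)
lambdaUm <- function(pas, diam_um) {
  sqrt((pas@rm * 1e3) * (diam_um * 1e-4) / (4 * pas@ra)) * 1e4
}

## analytic steady-state polarization of a sealed straight fiber in a
## uniform axial field, sign convention: anode at the +y end
fiberPolarization <- function(y_um, L_um, lambda_um, E_mVmm) {
  -(E_mVmm / 1000) * lambda_um *
    sinh((y_um - L_um / 2) / lambda_um) / cosh(L_um / (2 * lambda_um))
}

fix_tree <- buildArtificialNeuron()
fix_bio <- biophysics()
fix_pas <- passiveBiophysics()
fix_cfg <- solverConfig()
fix_sys <- compartmentalize(fix_tree, fix_bio, max_dx = fix_cfg@max_dx)
fix_init <- initSteadyState(fix_sys, fix_cfg)

## a small SWC fixture: soma, two dendritic branches up, axon chain down
swcFixtureText <- function() {
  c("# synthetic test morphology",
    "1 1 0 0 0 5 -1",
    "2 3 0 20 0 1 1",
    "3 3 -10 40 0 0.8 2",
    "4 3 10 40 0 0.8 2",
    "5 2 0 -30 0 1 1",
    "6 2 0 -60 0 1 5",
    "7 3 -20 60 0 0.6 3",
    "8 3 0 60 0 0.6 3",
    "9 3 20 60 0 0.6 4",
    "10 2 0 -90 0 1 6")
}

writeSWCFixture <- function(path = tempfile(fileext = ".swc")) {
  writeLines(swcFixtureText(), path)
  path
}
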