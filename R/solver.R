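## Discretization of a morphology into compartments and the simulate()
## front end over the compiled backward-Euler tree solver.

#' Compartmental system
#'
#' The discretized form of a morphology plus membrane: per-compartment
#' geometry, membrane capacitance and conductances, axial conductances to
#' parent compartments, and flattened gating kinetics.
#'
#' @slot comp data.frame: `section`, `kind`, `arc` (center fraction along the
#'   section), `x`, `y` (um), `len`, `diam`, `area` (um, um, um^2), `parent`
#'   (compartment index, 0 for the root), `g_axial` (uS, to parent),
#'   `path_dist` (um from the soma midpoint).
#' @slot gbar matrix ncomp x nchannel, peak conductances in uS.
#' @slot erev per-channel reversal potentials, mV.
#' @slot kin flattened gate table (internal layout).
#' @slot gleak,cm per-compartment leak conductance (uS) and capacitance (nF).
#' @slot eleak mV.
#' @slot tree the source [MorphologyTree-class].
#' @slot biophysics the [Biophysics-class] used.
#' @export
setClass("CompartmentalSystem",
  representation(comp = "data.frame", gbar = "matrix", erev = "numeric",
                 kin = "list", gleak = "numeric", cm = "numeric",
                 eleak = "numeric", tree = "MorphologyTree",
                 biophysics = "Biophysics")
)

setMethod("show", "CompartmentalSystem", function(object) {
  cat("CompartmentalSystem:", nrow(object@comp), "compartments,",
      length(object@erev), "active channel(s)\n")
  cat(sprintf("  dx range: %.2f-%.2f um\n", min(object@comp$len), max(object@comp$len)))
})

#' Field stimulus constructor
#'
#' @param amplitude mV/mm (signed; positive = anode on the +y side).
#' @param angle degrees between field and the y axis.
#' @param onset,offset ms.
#' @return A [FieldStimulus-class].
#' @export
fieldStimulus <- function(amplitude, angle = 0, onset = 100, offset = 600) {
  new("FieldStimulus", amplitude = amplitude, angle = angle,
      onset = onset, offset = offset)
}

#' EPSC stimulus constructor
#'
#' @param target_section section id (default the distal dendrite "dend8").
#' @param amplitude nA.
#' @param onset ms.
#' @param duration ms.
#' @param arc_position fraction along the section.
#' @return An [EPSCStimulus-class].
#' @export
epscStimulus <- function(target_section = "dend8", amplitude = 0.01,
                         onset = 100, duration = 500, arc_position = 0.5) {
  new("EPSCStimulus", target_section = target_section,
      arc_position = arc_position, amplitude = amplitude,
      onset = onset, duration = duration)
}

#' Solver configuration constructor
#'
#' @param dt ms (default 0.025).
#' @param max_dx um (default 10; every section gets an odd compartment count).
#' @param duration ms.
#' @param record_sites data.frame(section, arc).
#' @param steady_state_tolerance mV/ms.
#' @param record_stride record every this many steps.
#' @param use_tables use tabulated gating rates (fast path).
#' @return A [SolverConfig-class].
#' @export
solverConfig <- function(dt = 0.025, max_dx = 10, duration = 700,
                         record_sites = data.frame(section = "soma", arc = 0.5),
                         steady_state_tolerance = 1e-3,
                         record_stride = 1L, use_tables = TRUE) {
  cfg <- new("SolverConfig", dt = dt, max_dx = max_dx, duration = duration,
             record_sites = record_sites,
             steady_state_tolerance = steady_state_tolerance,
             use_tables = use_tables)
  attr(cfg, "record_stride") <- as.integer(record_stride)
  cfg
}

.recordStride <- function(config) {
  rs <- attr(config, "record_stride")
  if (is.null(rs)) 1L else rs
}

#' Discretize a morphology into a compartmental system
#'
#' Each section is split into an odd number of equal compartments of length
#' at most `max_dx` (so every section has a true midpoint compartment).
#' Axial conductance between adjacent compartment centers is the series
#' combination of the two half-compartment cytoplasmic resistances.
#'
#' @param tree a [MorphologyTree-class].
#' @param biophysics a [Biophysics-class].
#' @param max_dx um.
#' @return A [CompartmentalSystem-class].
#' @export
compartmentalize <- function(tree, biophysics, max_dx = 10) {
  validObject(tree)
  s <- tree@sections[match(.topoOrder(tree@sections), tree@sections$id), , drop = FALSE]
  pas <- biophysics@passive
  len_all <- sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2)

  rows <- vector("list", nrow(s))
  first_comp <- integer(nrow(s)); last_comp <- integer(nrow(s))
  mid_comp <- integer(nrow(s))
  idx <- 0L
  for (i in seq_len(nrow(s))) {
    L <- len_all[i]
    nc <- ceiling(L / max_dx)
    if (nc %% 2 == 0) nc <- nc + 1
    arc <- (seq_len(nc) - 0.5) / nc
    rows[[i]] <- data.frame(
      section = s$id[i], kind = s$kind[i], arc = arc,
      x = s$x0[i] + arc * (s$x1[i] - s$x0[i]),
      y = s$y0[i] + arc * (s$y1[i] - s$y0[i]),
      len = L / nc, diam = s$diam[i], stringsAsFactors = FALSE
    )
    first_comp[i] <- idx + 1L
    last_comp[i] <- idx + nc
    mid_comp[i] <- idx + (nc + 1L) %/% 2L
    idx <- idx + nc
  }
  comp <- do.call(rbind, rows)
  comp$area <- pi * comp$diam * comp$len
  n <- nrow(comp)

  ## axial links
  half_res <- function(j) pas@ra * 1e4 * (comp$len[j] / 2) / (pi * comp$diam[j]^2 / 4)
  parent <- integer(n); g_ax <- numeric(n)
  for (i in seq_len(nrow(s))) {
    f <- first_comp[i]; l <- last_comp[i]
    if (l > f) {
      for (j in (f + 1L):l) {
        parent[j] <- j - 1L
        g_ax[j] <- 1e6 / (half_res(j) + half_res(j - 1L))
      }
    }
    if (is.na(s$parent[i])) { parent[f] <- 0L; next }
    p <- match(s$parent[i], s$id)
    pc <- switch(s$attach_end[i],
                 proximal = first_comp[p], distal = last_comp[p],
                 center = mid_comp[p])
    extra <- if (s$attach_end[i] == "center") 0 else half_res(pc)
    parent[f] <- pc
    g_ax[f] <- 1e6 / (half_res(f) + extra)
  }
  comp$parent <- parent
  comp$g_axial <- g_ax

  ## path distances of compartment centers from the soma midpoint
  comp$path_dist <- vapply(seq_len(n), function(j) {
    pathDistanceFromSoma(tree, comp$section[j], comp$arc[j])
  }, numeric(1))

  ## membrane quantities (uS, nF)
  comp$cm_nF <- comp$area * pas@cm * 1e-5
  gleak <- comp$area * (1 / pas@rm) * 1e-5

  if (biophysics@passive_only || !length(biophysics@densities)) {
    gbar <- matrix(0, n, 0)
    erev <- numeric(0)
    kin <- list(gate_channel = integer(0), power = numeric(0),
                vhalf = numeric(0), k = numeric(0), tau_type = integer(0),
                tau_params = matrix(0, 0, 5), erev = numeric(0),
                channel_names = character(0))
  } else {
    kin <- .kineticsTable(biophysics@kinetics)
    keep <- names(biophysics@densities)
    if (!identical(sort(keep), sort(kin$channel_names))) {
      sel <- match(keep, kin$channel_names)
      if (anyNA(sel)) stop("density rule for unknown channel")
      gsel <- kin$gate_channel %in% (sel - 1L)
      remap <- match(kin$gate_channel, sel - 1L) - 1L
      kin <- list(gate_channel = remap[gsel], power = kin$power[gsel],
                  vhalf = kin$vhalf[gsel], k = kin$k[gsel],
                  tau_type = kin$tau_type[gsel],
                  tau_params = kin$tau_params[gsel, , drop = FALSE],
                  erev = kin$erev[sel], channel_names = keep)
    }
    gbar <- matrix(0, n, length(kin$channel_names))
    colnames(gbar) <- kin$channel_names
    for (ci in seq_along(kin$channel_names)) {
      rule <- biophysics@densities[[kin$channel_names[ci]]]
      dens <- densityAt(rule, comp$path_dist, comp$kind)
      gbar[, ci] <- dens * comp$area * 1e-6
    }
    erev <- kin$erev
  }

  new("CompartmentalSystem", comp = comp, gbar = gbar, erev = erev, kin = kin,
      gleak = gleak, cm = comp$cm_nF, eleak = pas@e_leak,
      tree = tree, biophysics = biophysics)
}

#' Extracellular potentials under a uniform field
#'
#' Potential at each compartment center is the field amplitude times the
#' distance along the field axis from the cathode reference plane (the
#' minimum projection for positive fields, the maximum for negative ones, so
#' the stored values are reproducible; only differences enter the dynamics).
#'
#' @param system a [CompartmentalSystem-class].
#' @param E field amplitude, mV/mm.
#' @param phi angle between field and y axis, degrees.
#' @return Numeric vector of per-compartment extracellular potentials, mV.
#' @export
extracellularPotentials <- function(system, E, phi = 0) {
  u <- .vextUnit(system, phi)
  if (E == 0) return(rep(0, nrow(system@comp)))
  ref <- if (E > 0) min(u) else max(u)
  E * (u - ref)
}

## projection of compartment centers on the field axis, mV per (mV/mm)
.vextUnit <- function(system, phi = 0) {
  a <- deg2rad(phi)
  (system@comp$x * sin(a) + system@comp$y * cos(a)) / 1000
}

#' Axial conductance between two adjacent compartments
#'
#' @param system a [CompartmentalSystem-class].
#' @param j,k compartment indices (must be adjacent in the tree).
#' @return Conductance in uS.
#' @export
axialConductance <- function(system, j, k) {
  comp <- system@comp
  if (comp$parent[j] == k) return(comp$g_axial[j])
  if (comp$parent[k] == j) return(comp$g_axial[k])
  stop("compartments ", j, " and ", k, " are not adjacent")
}

.gatesAt <- function(kin, v) {
  ngate <- length(kin$gate_channel)
  if (!ngate) return(matrix(0, length(v), 0))
  m <- matrix(0, length(v), ngate)
  for (g in seq_len(ngate)) {
    m[, g] <- 1 / (1 + exp((kin$vhalf[g] - v) / kin$k[g]))
  }
  m
}

#' Initialize the membrane at rest
#'
#' Relaxes the full system with no field and no injections until the largest
#' |dV/dt| falls below the tolerance; gating variables start at their steady
#' state for the leak reversal and settle with the voltage. For a passive
#' membrane the fixed point is the leak reversal exactly and no relaxation
#' run is needed.
#'
#' @param system a [CompartmentalSystem-class].
#' @param config a [SolverConfig-class].
#' @param t_max maximum relaxation time, ms.
#' @return list(v, gates, drift) with drift in mV/ms.
#' @export
initSteadyState <- function(system, config = solverConfig(), t_max = 5000) {
  n <- nrow(system@comp)
  ngate <- length(system@kin$gate_channel)
  if (ngate == 0L) {
    return(list(v = rep(system@eleak, n), gates = matrix(0, n, 0), drift = 0))
  }
  v <- rep(system@eleak, n)
  gates <- .gatesAt(system@kin, v)
  dt <- config@dt
  block <- 1000
  t_done <- 0
  drift <- Inf
  while (t_done < t_max) {
    out <- .rawSimulate(system, v0 = v, gates0 = gates, e_amp = 0,
                        e_on = 0, e_off = 1, inj = NULL, dt = dt,
                        duration = block, record_idx = 1L,
                        record_stride = max(1L, round(10 / dt)),
                        use_tables = config@use_tables)
    v <- out$v_final
    gates <- out$gates_final
    t_done <- t_done + block
    nt <- length(out$times)
    drift <- max(abs(out$v[nt, ] - out$v[nt - 1L, ])) /
      (out$times[nt] - out$times[nt - 1L])
    ## per-compartment drift via a short probe recording everything
    probe <- .rawSimulate(system, v0 = v, gates0 = gates, e_amp = 0,
                          e_on = 0, e_off = 1, inj = NULL, dt = dt,
                          duration = 10, record_idx = seq_len(n),
                          record_stride = max(1L, round(10 / dt)),
                          use_tables = config@use_tables)
    nt <- length(probe$times)
    drift <- max(abs(probe$v[nt, ] - probe$v[1, ])) / (probe$times[nt] - probe$times[1])
    v <- probe$v_final
    gates <- probe$gates_final
    if (drift < config@steady_state_tolerance) {
      return(list(v = v, gates = gates, drift = drift))
    }
  }
  stop(sprintf("initialization failed to converge: residual drift %.3g mV/ms after %g ms",
               drift, t_max))
}

## thin wrapper over the compiled stepper
.rawSimulate <- function(system, v0, gates0, e_amp, e_on, e_off, inj,
                         dt, duration, record_idx, record_stride = 1L,
                         use_tables = TRUE, phi = 0, track_residual = FALSE,
                         vext_offset = 0) {
  nsteps <- as.integer(round(duration / dt))
  if (is.null(inj)) {
    inj <- list(comp = integer(0), amp = numeric(0),
                on = numeric(0), off = numeric(0))
  }
  out <- cpp_simulate(
    parent = as.integer(system@comp$parent) - 1L,
    g_axial = system@comp$g_axial,
    cm = system@cm, gleak = system@gleak, eleak = system@eleak,
    gbar = system@gbar, erev = system@erev,
    gate_channel = as.integer(system@kin$gate_channel),
    gate_power = as.numeric(system@kin$power),
    gate_vhalf = as.numeric(system@kin$vhalf),
    gate_k = as.numeric(system@kin$k),
    tau_type = as.integer(system@kin$tau_type),
    tau_params = system@kin$tau_params,
    vext_unit = .vextUnit(system, phi) + vext_offset,
    e_amp = e_amp, e_on = e_on, e_off = e_off,
    inj_comp = as.integer(inj$comp) - 1L, inj_amp = inj$amp,
    inj_on = inj$on, inj_off = inj$off,
    dt = dt, nsteps = nsteps, v0 = v0, gates0 = gates0,
    record_idx = as.integer(record_idx) - 1L,
    record_stride = as.integer(record_stride),
    use_tables = use_tables, track_residual = track_residual
  )
  out
}

## map record sites (section, arc) to compartment indices
.siteIndices <- function(system, record_sites) {
  comp <- system@comp
  vapply(seq_len(nrow(record_sites)), function(i) {
    sec <- record_sites$section[i]
    j <- which(comp$section == sec)
    if (!length(j)) stop("unknown recording site section: ", sec)
    j[which.min(abs(comp$arc[j] - record_sites$arc[i]))]
  }, integer(1))
}

#' Simulate the field-coupled cable system
#'
#' Advances the coupled voltage/gating system with a backward-Euler tree
#' solve; the extracellular field contributes the axial source current
#' g_ax * (V_ext,k - V_ext,j) between adjacent compartments while it is on.
#'
#' @param x a [MorphologyTree-class] or a prebuilt [CompartmentalSystem-class].
#' @param biophysics a [Biophysics-class] (ignored if `x` is a system).
#' @param field a [FieldStimulus-class].
#' @param injections an [EPSCStimulus-class], or a list of them, or NULL.
#' @param config a [SolverConfig-class].
#' @param init optional initial state from [initSteadyState()].
#' @param record "sites" (the configured recording sites) or "all".
#' @param track_residual also track the per-step linear-system residual
#'   (reported in `info$max_residual`).
#' @return A [Trace-class].
#' @export
simulate <- function(x, biophysics = NULL, field = fieldStimulus(0),
                     injections = NULL, config = solverConfig(),
                     init = NULL, record = c("sites", "all"),
                     track_residual = FALSE) {
  record <- match.arg(record)
  system <- if (is(x, "CompartmentalSystem")) x else {
    compartmentalize(x, biophysics, max_dx = config@max_dx)
  }
  if (is.null(init)) init <- initSteadyState(system, config)
  if (is(injections, "EPSCStimulus")) injections <- list(injections)
  inj <- NULL
  if (length(injections)) {
    comp_idx <- vapply(injections, function(e) {
      .siteIndices(system, data.frame(section = e@target_section,
                                      arc = e@arc_position))
    }, integer(1))
    inj <- list(comp = comp_idx,
                amp = vapply(injections, function(e) e@amplitude, numeric(1)),
                on = vapply(injections, function(e) e@onset, numeric(1)),
                off = vapply(injections, function(e) e@onset + e@duration, numeric(1)))
  }
  sites <- if (record == "all") {
    data.frame(section = system@comp$section, arc = system@comp$arc)
  } else config@record_sites
  ridx <- if (record == "all") seq_len(nrow(system@comp)) else .siteIndices(system, sites)

  out <- .rawSimulate(system, v0 = init$v, gates0 = init$gates,
                      e_amp = field@amplitude, e_on = field@onset,
                      e_off = field@offset, inj = inj,
                      dt = config@dt, duration = config@duration,
                      record_idx = ridx, record_stride = .recordStride(config),
                      use_tables = config@use_tables, phi = field@angle,
                      track_residual = track_residual)
  if (isTRUE(out$diverged)) {
    j <- out$diverge_comp
    stop(sprintf("solver diverged (|V| > 500 mV) at t = %.3f ms in section '%s' (arc %.2f)",
                 out$diverge_time, system@comp$section[j], system@comp$arc[j]))
  }
  vu <- .vextUnit(system, field@angle)
  new("Trace", times = out$times, v = out$v,
      sites = data.frame(sites, comp = ridx),
      vext = vu[ridx],
      info = list(field = field, dt = config@dt,
                  max_residual = out$max_residual,
                  final_state = list(v = out$v_final, gates = out$gates_final)))
}

setMethod("show", "Trace", function(object) {
  cat("Trace:", length(object@times), "samples,", ncol(object@v), "site(s),",
      sprintf("t in [%.1f, %.1f] ms\n", min(object@times), max(object@times)))
})

#' Tidy data.frame view of a trace
#'
#' @param x a [Trace-class].
#' @param ... unused.
#' @return data.frame(time, site, section, arc, v).
#' @export
traceToDataFrame <- function(x, ...) {
  n <- ncol(x@v)
  site_lab <- paste0(x@sites$section, "@", format(x@sites$arc, digits = 3))
  data.frame(
    time = rep(x@times, n),
    site = rep(site_lab, each = length(x@times)),
    section = rep(x@sites$section, each = length(x@times)),
    arc = rep(x@sites$arc, each = length(x@times)),
    v = as.vector(x@v)
  )
}

#' Export a trace as tidy CSV
#'
#' Deterministic column order (time, site, section, arc, v).
#'
#' @param trace a [Trace-class].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeTraceCSV <- function(trace, path) {
  write.csv(traceToDataFrame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Steady-state polarization profile under a subthreshold field
#'
#' Turns the field on from a settled baseline, lets the membrane settle
#' again, and returns the per-compartment change in transmembrane potential.
#' An error is raised if any compartment spikes (crosses 0 mV) during the
#' settling run.
#'
#' @param x tree or [CompartmentalSystem-class].
#' @param biophysics a [Biophysics-class] (when `x` is a tree).
#' @param E field amplitude, mV/mm.
#' @param config a [SolverConfig-class].
#' @param settle settling time with the field on, ms.
#' @param init optional baseline state.
#' @return data.frame(section, arc, x, y, delta_v) with the soma-midpoint
#'   polarization in attribute "soma_delta_v".
#' @export
steadyStatePolarization <- function(x, biophysics = NULL, E,
                                    config = solverConfig(), settle = 400,
                                    init = NULL) {
  system <- if (is(x, "CompartmentalSystem")) x else {
    compartmentalize(x, biophysics, max_dx = config@max_dx)
  }
  if (is.null(init)) init <- initSteadyState(system, config)
  n <- nrow(system@comp)
  out <- .rawSimulate(system, v0 = init$v, gates0 = init$gates,
                      e_amp = E, e_on = 0, e_off = settle + 1, inj = NULL,
                      dt = config@dt, duration = settle,
                      record_idx = seq_len(n),
                      record_stride = max(1L, round(5 / config@dt)),
                      use_tables = config@use_tables)
  if (isTRUE(out$diverged) || out$v_max > 0) {
    stop("suprathreshold field: membrane spiked during polarization settling")
  }
  nt <- length(out$times)
  drift <- max(abs(out$v[nt, ] - out$v[nt - 1L, ])) / (out$times[nt] - out$times[nt - 1L])
  if (drift > config@steady_state_tolerance) {
    warning(sprintf("polarization not fully settled: drift %.3g mV/ms", drift))
  }
  dv <- out$v_final - init$v
  res <- data.frame(section = system@comp$section, arc = system@comp$arc,
                    x = system@comp$x, y = system@comp$y, delta_v = dv)
  soma_mid <- .siteIndices(system, data.frame(section = "soma", arc = 0.5))
  attr(res, "soma_delta_v") <- dv[soma_mid]
  res
}
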