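## Stimulation protocols: spike detection, EF threshold search, f-E curves,
## morphology sweeps, EPSC co-stimulation, AP diagnostics, polarization fits.

#' Detect spikes in a recorded trace
#'
#' Upward crossings of the detection threshold separated by at least the
#' refractory period.
#'
#' @param trace a [Trace-class].
#' @param site site index, or a section id (the recorded site on that section
#'   with arc closest to 0.5 is used).
#' @param threshold detection threshold, mV (default -10).
#' @param refractory ms (default 2).
#' @return A [SpikeTrain-class].
#' @export
detectSpikes <- function(trace, site = "soma", threshold = -10, refractory = 2) {
  if (is.character(site)) {
    j <- which(trace@sites$section == site)
    if (!length(j)) stop("unknown site: ", site)
    site <- j[which.min(abs(trace@sites$arc[j] - 0.5))]
  }
  if (site < 1 || site > ncol(trace@v)) stop("site index out of range")
  v <- trace@v[, site]
  t <- trace@times
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  times <- numeric(0)
  last <- -Inf
  for (i in up) {
    ## linear interpolation of the crossing time
    f <- (threshold - v[i - 1L]) / (v[i] - v[i - 1L])
    tc <- t[i - 1L] + f * (t[i] - t[i - 1L])
    if (tc - last >= refractory) {
      times <- c(times, tc)
      last <- tc
    }
  }
  new("SpikeTrain", spike_times = times, detection_threshold = threshold,
      refractory = refractory)
}

#' Number of detected spikes
#' @param spikes a [SpikeTrain-class].
#' @export
nSpikes <- function(spikes) length(spikes@spike_times)

setMethod("show", "SpikeTrain", function(object) {
  cat("SpikeTrain:", length(object@spike_times), "spike(s)")
  if (length(object@spike_times)) {
    cat(sprintf(", first at %.2f ms", object@spike_times[1]))
  }
  cat("\n")
})

#' Firing rate over a window
#'
#' @param spikes a [SpikeTrain-class].
#' @param window length-2 numeric (ms); spikes in (window[1], window[2]] count.
#' @return Rate in Hz.
#' @export
firingRate <- function(spikes, window) {
  if (length(window) != 2L || window[2] <= window[1]) {
    stop("window must be a well-ordered pair of times")
  }
  st <- spikes@spike_times
  1000 * sum(st > window[1] & st <= window[2]) / (window[2] - window[1])
}

## one simulation -> spike count at the soma midpoint
.spikeCount <- function(system, init, E, config, inj = NULL, onset, offset,
                        detect_threshold = -10, refractory = 2) {
  soma <- .siteIndices(system, data.frame(section = "soma", arc = 0.5))
  out <- .rawSimulate(system, v0 = init$v, gates0 = init$gates,
                      e_amp = E, e_on = onset, e_off = offset, inj = inj,
                      dt = config@dt, duration = config@duration,
                      record_idx = soma, record_stride = .recordStride(config),
                      use_tables = config@use_tables)
  if (isTRUE(out$diverged)) {
    stop(sprintf("solver diverged (|V| > 500 mV) at t = %.3f ms (E = %g mV/mm)",
                 out$diverge_time, E))
  }
  tr <- new("Trace", times = out$times, v = out$v,
            sites = data.frame(section = "soma", arc = 0.5, comp = soma))
  nSpikes(detectSpikes(tr, site = 1L, threshold = detect_threshold,
                       refractory = refractory))
}

.asInjection <- function(system, epsc) {
  if (is.null(epsc)) return(NULL)
  comp <- .siteIndices(system, data.frame(section = epsc@target_section,
                                          arc = epsc@arc_position))
  list(comp = comp, amp = epsc@amplitude, on = epsc@onset,
       off = epsc@onset + epsc@duration)
}

#' Find the EF firing threshold
#'
#' Stepwise coarse scan of increasing field magnitude until an action
#' potential is initiated, then bisection of the bracketing interval down to
#' the requested resolution. Spikes are detected at the soma midpoint.
#'
#' @param x a [MorphologyTree-class] or [CompartmentalSystem-class].
#' @param biophysics a [Biophysics-class] (when `x` is a tree).
#' @param polarity "+" or "-".
#' @param e_max maximum field magnitude scanned, mV/mm.
#' @param resolution mV/mm.
#' @param coarse_step mV/mm for the initial scan.
#' @param config a [SolverConfig-class]; the field is applied between
#'   `onset` and `offset`.
#' @param onset,offset field timing, ms.
#' @param epsc optional [EPSCStimulus-class] co-applied with the field.
#' @param init optional initial state.
#' @return A [ThresholdResult-class]; when no spike occurs up to `e_max` the
#'   result has `found = FALSE` and an NA threshold.
#' @export
findEFThreshold <- function(x, biophysics = NULL, polarity = c("+", "-"),
                            e_max = 2000, resolution = 0.5, coarse_step = 10,
                            config = solverConfig(), onset = 100, offset = 600,
                            epsc = NULL, init = NULL) {
  polarity <- match.arg(polarity)
  sgn <- if (polarity == "+") 1 else -1
  system <- if (is(x, "CompartmentalSystem")) x else {
    compartmentalize(x, biophysics, max_dx = config@max_dx)
  }
  if (is.null(init)) init <- initSteadyState(system, config)
  inj <- .asInjection(system, epsc)

  log_e <- numeric(0); log_n <- integer(0)
  count_at <- function(Emag) {
    n <- .spikeCount(system, init, sgn * Emag, config, inj, onset, offset)
    log_e <<- c(log_e, sgn * Emag); log_n <<- c(log_n, n)
    n
  }
  if (count_at(0) > 0) {
    stop("neuron is not quiescent without field stimulation")
  }
  lo <- 0; hi <- NA_real_
  e <- coarse_step
  while (e <= e_max + 1e-9) {
    if (count_at(e) >= 1L) { hi <- e; break }
    lo <- e
    e <- e + coarse_step
  }
  if (is.na(hi)) {
    return(new("ThresholdResult", polarity = polarity,
               e_threshold = NA_real_, found = FALSE, resolution = resolution,
               bracket = c(sgn * lo, NA_real_),
               search_log = data.frame(E = log_e, n_spikes = log_n)))
  }
  while (hi - lo > resolution) {
    mid <- (hi + lo) / 2
    if (count_at(mid) >= 1L) hi <- mid else lo <- mid
  }
  new("ThresholdResult", polarity = polarity, e_threshold = sgn * hi,
      found = TRUE, resolution = resolution, bracket = c(sgn * lo, sgn * hi),
      search_log = data.frame(E = log_e, n_spikes = log_n))
}

setMethod("show", "ThresholdResult", function(object) {
  if (object@found) {
    cat(sprintf("ThresholdResult: E_threshold = %.1f mV/mm (polarity %s, resolution %.2g)\n",
                object@e_threshold, object@polarity, object@resolution))
  } else {
    cat(sprintf("ThresholdResult: no threshold found up to %.1f mV/mm (polarity %s)\n",
                max(abs(object@search_log$E)), object@polarity))
  }
  cat("  simulations:", nrow(object@search_log), "\n")
})

#' Firing rate versus field curve
#'
#' @param x tree or system.
#' @param biophysics a [Biophysics-class] (when `x` is a tree).
#' @param e_grid field amplitudes, mV/mm (signed; sorted internally).
#' @param config a [SolverConfig-class].
#' @param onset,offset field window, ms; rates are computed over this window.
#' @param init optional initial state.
#' @return An [FECurve-class].
#' @export
fECurve <- function(x, biophysics = NULL, e_grid, config = solverConfig(),
                    onset = 100, offset = 600, init = NULL) {
  system <- if (is(x, "CompartmentalSystem")) x else {
    compartmentalize(x, biophysics, max_dx = config@max_dx)
  }
  if (is.null(init)) init <- initSteadyState(system, config)
  e_grid <- sort(e_grid)
  soma <- .siteIndices(system, data.frame(section = "soma", arc = 0.5))
  f <- vapply(e_grid, function(E) {
    out <- .rawSimulate(system, v0 = init$v, gates0 = init$gates,
                        e_amp = E, e_on = onset, e_off = offset, inj = NULL,
                        dt = config@dt, duration = config@duration,
                        record_idx = soma, record_stride = .recordStride(config),
                        use_tables = config@use_tables)
    if (isTRUE(out$diverged)) stop("solver diverged at E = ", E)
    tr <- new("Trace", times = out$times, v = out$v,
              sites = data.frame(section = "soma", arc = 0.5, comp = soma))
    firingRate(detectSpikes(tr, site = 1L), c(onset, offset))
  }, numeric(1))
  new("FECurve", table = data.frame(E = e_grid, f = f), window = c(onset, offset))
}

setMethod("show", "FECurve", function(object) {
  cat("FECurve:", nrow(object@table), "field values, window",
      sprintf("(%.0f, %.0f] ms\n", object@window[1], object@window[2]))
})

#' EF threshold in the presence of an EPSC
#'
#' Same search as [findEFThreshold()] with a rectangular current pulse
#' co-applied; errors if the EPSC alone (no field) already evokes a spike.
#'
#' @inheritParams findEFThreshold
#' @param epsc an [EPSCStimulus-class].
#' @return A [ThresholdResult-class].
#' @export
thresholdWithEPSC <- function(x, biophysics = NULL, epsc,
                              polarity = c("+", "-"), e_max = 2000,
                              resolution = 0.5, coarse_step = 10,
                              config = solverConfig(), onset = 100,
                              offset = 600, init = NULL) {
  polarity <- match.arg(polarity)
  system <- if (is(x, "CompartmentalSystem")) x else {
    compartmentalize(x, biophysics, max_dx = config@max_dx)
  }
  if (is.null(init)) init <- initSteadyState(system, config)
  inj <- .asInjection(system, epsc)
  n0 <- .spikeCount(system, init, 0, config, inj, onset, offset)
  if (n0 > 0) stop("EPSC alone evokes a spike; it must be subthreshold")
  findEFThreshold(system, polarity = polarity, e_max = e_max,
                  resolution = resolution, coarse_step = coarse_step,
                  config = config, onset = onset, offset = offset,
                  epsc = epsc, init = init)
}

#' AP peak and initiation-site diagnostics
#'
#' Requires a trace recorded at all compartments (record = "all"). Reports
#' the per-site maximum voltage during the first action potential and the
#' site whose (interpolated) threshold crossing is earliest.
#'
#' @param trace a [Trace-class] with all compartments recorded.
#' @param threshold detection threshold, mV.
#' @return list(site_peaks = data.frame(section, arc, peak),
#'   initiation = list(section, arc, time)).
#' @export
apSiteDiagnostics <- function(trace, threshold = -10) {
  v <- trace@v; t <- trace@times
  cross_time <- rep(NA_real_, ncol(v))
  for (s in seq_len(ncol(v))) {
    i <- which(v[-1, s] >= threshold & v[-nrow(v), s] < threshold)
    if (length(i)) {
      i <- i[1] + 1L
      f <- (threshold - v[i - 1L, s]) / (v[i, s] - v[i - 1L, s])
      cross_time[s] <- t[i - 1L] + f * (t[i] - t[i - 1L])
    }
  }
  if (all(is.na(cross_time))) stop("no spike in trace")
  t0 <- min(cross_time, na.rm = TRUE)
  win <- t >= t0 - 2 & t <= t0 + 8
  peaks <- apply(v[win, , drop = FALSE], 2, max)
  init_site <- which.min(cross_time)
  list(
    site_peaks = data.frame(section = trace@sites$section,
                            arc = trace@sites$arc, peak = peaks),
    initiation = list(section = trace@sites$section[init_site],
                      arc = trace@sites$arc[init_site], time = t0)
  )
}

#' Somatic polarization slope versus field
#'
#' Fits a least-squares line to the somatic steady-state polarization over a
#' subthreshold field grid.
#'
#' @param x tree or system.
#' @param biophysics a [Biophysics-class] (when `x` is a tree).
#' @param e_grid field amplitudes, mV/mm (all must be subthreshold).
#' @param config a [SolverConfig-class].
#' @param settle settling time, ms.
#' @return list(slope (mV per mV/mm), residual_max, table).
#' @export
polarizationVsE <- function(x, biophysics = NULL, e_grid,
                            config = solverConfig(), settle = 400) {
  system <- if (is(x, "CompartmentalSystem")) x else {
    compartmentalize(x, biophysics, max_dx = config@max_dx)
  }
  init <- initSteadyState(system, config)
  dv <- vapply(e_grid, function(E) {
    attr(steadyStatePolarization(system, E = E, config = config,
                                 settle = settle, init = init),
         "soma_delta_v")
  }, numeric(1))
  fit <- lm(dv ~ e_grid)
  list(slope = unname(coef(fit)[2]), residual_max = max(abs(resid(fit))),
       table = data.frame(E = e_grid, soma_delta_v = dv))
}
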