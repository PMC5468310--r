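## Membrane biophysics: passive constants, distance-dependent channel
## density rules, and pluggable gating kinetics.

#' Create passive membrane parameters
#'
#' @param cm uF/cm^2.
#' @param ra Ohm cm.
#' @param rm kOhm cm^2.
#' @param e_leak mV.
#' @return A [PassiveParams-class] object.
#' @export
passiveParams <- function(cm = 1, ra = 80, rm = 28, e_leak = -65) {
  new("PassiveParams", cm = cm, ra = ra, rm = rm, e_leak = e_leak)
}

#' Create a channel density rule
#'
#' @param channel channel name.
#' @param somatic pS/um^2 at the soma.
#' @param slope pS/um^2 per 100 um of path distance.
#' @param dendritic_only whether the slope applies only on dendrites.
#' @return A [ChannelDensityRule-class] object.
#' @export
channelDensityRule <- function(channel, somatic, slope = 0, dendritic_only = TRUE) {
  new("ChannelDensityRule", channel = channel, somatic = somatic,
      slope = slope, dendritic_only = dendritic_only)
}

#' Default channel density rules
#'
#' Transient Na and delayed-rectifier K are uniform at 200 and 100 pS/um^2.
#' The A-type K density is 250 pS/um^2 at the soma and rises by 250 pS/um^2
#' per 100 um of path distance on dendrites; the h current rises from
#' 0.5 pS/um^2 by 1.5 pS/um^2 per 100 um on dendrites. Axonal sections use
#' the somatic densities.
#'
#' @return Named list of [ChannelDensityRule-class] objects.
#' @export
defaultDensityRules <- function() {
  list(
    na  = channelDensityRule("na", 200, 0, FALSE),
    kdr = channelDensityRule("kdr", 100, 0, FALSE),
    ka  = channelDensityRule("ka", 250, 250, TRUE),
    h   = channelDensityRule("h", 0.5, 1.5, TRUE)
  )
}

#' Evaluate a density rule at a path distance
#'
#' @param rule a [ChannelDensityRule-class].
#' @param dist path distance from the soma midpoint, um (>= 0).
#' @param kind section kind at the queried point (the slope applies only on
#'   dendritic kinds when the rule is `dendritic_only`).
#' @return Peak conductance density, pS/um^2.
#' @export
densityAt <- function(rule, dist, kind = "soma") {
  if (any(dist < 0)) stop("path distance must be >= 0")
  dendritic <- kind %in% c("dend_proximal", "dend_distal")
  if (rule@dendritic_only && !all(dendritic)) {
    ifelse(dendritic, rule@somatic + rule@slope * dist / 100, rule@somatic)
  } else if (rule@dendritic_only) {
    rule@somatic + rule@slope * dist / 100
  } else {
    rep(rule@somatic + 0 * dist, length.out = length(dist))
  }
}

## ---- kinetic schemes -------------------------------------------------------

#' Read a kinetic scheme from a structured parameter file
#'
#' The file is YAML with a `reversals` block (mV) and a `channels` block;
#' each channel has a `reversal` key naming a reversal potential and a
#' `gates` list. Each gate has `power`, an `inf` block (`vhalf`, `k`: the
#' steady state is 1/(1+exp((vhalf-v)/k)), negative `k` for inactivation)
#' and a `tau` block (`type: constant` with `tau0`, or `type: bell` with
#' `min`, `amp`, `vmax`, `k1`, `k2`: tau = min + amp/(exp((v-vmax)/k1) +
#' exp(-(v-vmax)/k2)), ms).
#'
#' @param path YAML file.
#' @return A [KineticScheme-class] object.
#' @export
readKineticScheme <- function(path) {
  spec <- yaml::read_yaml(path)
  for (key in c("name", "version", "reversals", "channels")) {
    if (is.null(spec[[key]])) stop("kinetic scheme file missing key: ", key)
  }
  rev <- unlist(spec$reversals)
  chans <- spec$channels
  for (cn in names(chans)) {
    ## YAML 1.1 parses bare y/n as booleans; recover them as gate names
    chans[[cn]]$gates <- lapply(chans[[cn]]$gates, function(g) {
      if (is.logical(g$name)) g$name <- if (g$name) "y" else "n"
      g
    })
    ch <- chans[[cn]]
    if (is.null(ch$reversal) || !(ch$reversal %in% names(rev))) {
      stop("channel '", cn, "' has no valid reversal reference")
    }
    if (!length(ch$gates)) stop("channel '", cn, "' has no gates")
    for (g in ch$gates) {
      if (is.null(g$name) || is.null(g$power) || is.null(g$inf) || is.null(g$tau)) {
        stop("channel '", cn, "': each gate needs name, power, inf, tau")
      }
      if (g$inf$k == 0) stop("channel '", cn, "': inf slope k must be nonzero")
      tt <- g$tau$type
      if (!tt %in% c("constant", "bell")) stop("unknown tau type: ", tt)
      if (tt == "constant" && g$tau$tau0 <= 0) stop("tau0 must be positive")
      if (tt == "bell" && g$tau$min <= 0) stop("tau min must be positive")
    }
  }
  new("KineticScheme",
      name = as.character(spec$name), version = as.character(spec$version),
      reversals = rev, channels = chans, path = normalizePath(path),
      hash = unname(tools::md5sum(path)))
}

#' The default CA1-pyramidal-flavored kinetic scheme
#'
#' Loads the scheme shipped in `inst/extdata/kinetics/ca1_default.yaml`:
#' transient Na (m^3 h), delayed-rectifier K, A-type K with inactivation, and
#' the hyperpolarization-activated h current.
#'
#' @return A [KineticScheme-class] object.
#' @export
defaultKineticScheme <- function() {
  readKineticScheme(system.file("extdata", "kinetics", "ca1_default.yaml",
                                package = "cableEF", mustWork = TRUE))
}

#' Gate steady state and time constant
#'
#' Reference (R-level) evaluation of a gate's steady state and time constant;
#' the solver evaluates the same expressions.
#'
#' @param gate a gate entry from a [KineticScheme-class] channel.
#' @param v membrane potential, mV (vectorized).
#' @return Numeric vector.
#' @export
gateInf <- function(gate, v) 1 / (1 + exp((gate$inf$vhalf - v) / gate$inf$k))

#' @rdname gateInf
#' @export
gateTau <- function(gate, v) {
  tt <- gate$tau
  if (tt$type == "constant") {
    rep(tt$tau0, length.out = length(v))
  } else {
    tt$min + tt$amp / (exp((v - tt$vmax) / tt$k1) + exp(-(v - tt$vmax) / tt$k2))
  }
}

## flat gate table consumed by the C++ stepper
.kineticsTable <- function(scheme) {
  rev <- scheme@reversals
  gate_channel <- integer(0); power <- numeric(0)
  vhalf <- numeric(0); kk <- numeric(0)
  tau_type <- integer(0); tau_p <- matrix(0, 0, 5)
  erev <- numeric(0); channel_names <- character(0)
  ci <- 0L
  for (cn in names(scheme@channels)) {
    ch <- scheme@channels[[cn]]
    ci <- ci + 1L
    channel_names[ci] <- cn
    erev[ci] <- rev[[ch$reversal]]
    for (g in ch$gates) {
      gate_channel <- c(gate_channel, ci - 1L)
      power <- c(power, g$power)
      vhalf <- c(vhalf, g$inf$vhalf)
      kk <- c(kk, g$inf$k)
      if (g$tau$type == "constant") {
        tau_type <- c(tau_type, 0L)
        tau_p <- rbind(tau_p, c(g$tau$tau0, 0, 0, 1, 1))
      } else {
        tau_type <- c(tau_type, 1L)
        tau_p <- rbind(tau_p, c(g$tau$min, g$tau$amp, g$tau$vmax, g$tau$k1, g$tau$k2))
      }
    }
  }
  list(gate_channel = gate_channel, power = power, vhalf = vhalf, k = kk,
       tau_type = tau_type, tau_params = tau_p, erev = erev,
       channel_names = channel_names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create a biophysics bundle
#'
#' @param passive a [PassiveParams-class].
#' @param densities named list of [ChannelDensityRule-class] objects; names
#'   must match channel names in the kinetic scheme.
#' @param kinetics a [KineticScheme-class].
#' @param passive_only drop all active conductances.
#' @return A [Biophysics-class] object.
#' @export
biophysics <- function(passive = passiveParams(),
                       densities = defaultDensityRules(),
                       kinetics = defaultKineticScheme(),
                       passive_only = FALSE) {
  obj <- new("Biophysics", passive = passive, densities = densities,
             kinetics = kinetics, passive_only = passive_only)
  if (!passive_only) {
    miss <- setdiff(names(densities), names(kinetics@channels))
    if (length(miss)) {
      stop("density rules without kinetics: ", paste(miss, collapse = ", "))
    }
  }
  obj
}

## default bundle without shadowing issues where `biophysics` is an argument
.defaultBiophysics <- function() biophysics()

#' Passive-only biophysics (leaky cable)
#'
#' @param passive a [PassiveParams-class].
#' @return A [Biophysics-class] with no active conductances.
#' @export
passiveBiophysics <- function(passive = passiveParams()) {
  biophysics(passive = passive, densities = list(),
             kinetics = new("KineticScheme", name = "none", version = "0",
                            reversals = c(none = 0), channels = list(),
                            path = "", hash = ""),
             passive_only = TRUE)
}

#' Total membrane current density
#'
#' Reference implementation of the per-area membrane current
#' I = sum_c g_c * prod(gates^p) * (V - E_c) + (V - E_leak)/Rm, used for
#' tests and diagnostics; the solver computes the same quantity compartment
#' by compartment.
#'
#' @param v membrane potential, mV.
#' @param gates named list: per channel, named numeric vector of gate values.
#' @param densities named numeric, peak densities in pS/um^2 per channel.
#' @param scheme a [KineticScheme-class].
#' @param passive a [PassiveParams-class].
#' @return Current density in uA/cm^2 (positive = outward).
#' @export
membraneCurrent <- function(v, gates, densities, scheme, passive) {
  ## leak: 1/rm with rm in kOhm cm^2 is a conductance density in mS/cm^2
  i <- (1 / passive@rm) * (v - passive@e_leak)
  for (cn in names(densities)) {
    ch <- scheme@channels[[cn]]
    g_ms <- psum2_to_mscm2(densities[[cn]])
    open <- 1
    for (g in ch$gates) open <- open * gates[[cn]][[g$name]]^g$power
    erev <- scheme@reversals[[ch$reversal]]
    i <- i + g_ms * open * (v - erev)
  }
  i
}

#' Convert pS/um^2 to mS/cm^2
#'
#' The identity 1 pS/um^2 == 0.1 mS/cm^2; this is the only place the
#' conversion is implemented.
#'
#' @param x density in pS/um^2.
#' @return Density in mS/cm^2.
#' @export
psum2_to_mscm2 <- function(x) 0.1 * x
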