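## Central S4 classes. Sections are stored as a data.frame rather than a list
## of objects: every algorithm downstream (discretization, serialization,
## sweeps) is column-oriented.

SECTION_KINDS <- c("soma", "axon", "axon_terminal", "dend_proximal", "dend_distal")
ATTACH_ENDS <- c("proximal", "distal", "center")

#' Branched neuron morphology
#'
#' A rooted tree of cylindrical sections with planar (x, y) coordinates.
#' The y axis is the somato-dendritic axis (dendrites toward +y, axon toward
#' -y); z is not represented, matching the strictly two-dimensional geometry
#' used throughout the package. Exactly one section (the soma) has no parent;
#' every other section attaches at its proximal point to an end (or, for
#' somatic attachment of reconstructed cells, the midpoint) of its parent.
#'
#' @slot sections data.frame with columns `id`, `kind` (one of soma, axon,
#'   axon_terminal, dend_proximal, dend_distal), `x0`, `y0` (proximal point,
#'   um), `x1`, `y1` (distal point, um), `diam` (um), `parent` (id or NA),
#'   `attach_end` ("proximal", "distal" or "center" of the parent).
#' @slot metadata list of free-form labels (e.g. the builder parameters).
#' @export
setClass("MorphologyTree",
  representation(sections = "data.frame", metadata = "list"),
  prototype(metadata = list())
)

setValidity("MorphologyTree", function(object) {
  s <- object@sections
  need <- c("id", "kind", "x0", "y0", "x1", "y1", "diam", "parent", "attach_end")
  if (!all(need %in% names(s))) {
    return(paste("sections must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(s) == 0L) return("morphology has no sections")
  if (anyDuplicated(s$id)) return("section ids must be unique")
  if (!all(s$kind %in% SECTION_KINDS)) return("unknown section kind")
  if (any(!is.finite(s$x0) | !is.finite(s$y0) | !is.finite(s$x1) | !is.finite(s$y1))) {
    return("section coordinates must be finite")
  }
  if (any(s$diam <= 0)) return("section diameters must be positive")
  len <- sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2)
  if (any(len <= 0)) return("section lengths must be positive")
  root <- which(is.na(s$parent))
  if (length(root) != 1L) return("exactly one section (the soma) must have no parent")
  if (s$kind[root] != "soma") return("the root section must be the soma")
  if (!all(s$parent[-root] %in% s$id)) return("dangling parent reference")
  if (!all(s$attach_end[-root] %in% ATTACH_ENDS)) return("attach_end must be proximal, distal or center")
  ## connectivity + acyclicity: walk every section up to the root
  idx <- match(s$parent, s$id)
  for (i in seq_len(nrow(s))) {
    j <- i; hops <- 0L
    while (!is.na(idx[j])) {
      j <- idx[j]; hops <- hops + 1L
      if (hops > nrow(s)) return("cycle in parent links")
    }
    if (j != root) return("section not connected to the soma")
  }
  ## geometric attachment
  for (i in seq_len(nrow(s))[-root]) {
    p <- idx[i]
    ap <- switch(s$attach_end[i],
      proximal = c(s$x0[p], s$y0[p]),
      distal   = c(s$x1[p], s$y1[p]),
      center   = c((s$x0[p] + s$x1[p]) / 2, (s$y0[p] + s$y1[p]) / 2)
    )
    if (max(abs(c(s$x0[i], s$y0[i]) - ap)) > 1e-6) {
      return(sprintf("section '%s' does not start at its attachment point", s$id[i]))
    }
  }
  TRUE
})

#' Parameters of the artificial pyramidal-like neuron
#'
#' Defaults give the reference cell: a 10 x 10 um soma, a 50 um x 2 um axon
#' toward -y, and 12 dendrites toward +y (4 proximal of 8 um attached to the
#' soma, 8 distal of 2 um attached pairwise to the proximal ones), all 1 um in
#' diameter, with no bends or branches. Angles are in degrees and measured
#' away from the somato-dendritic (y) axis.
#'
#' @slot soma_length,soma_diameter um.
#' @slot axon_length,axon_diameter um.
#' @slot proximal_dend_length,distal_dend_length um.
#' @slot dend_diameter um; `proximal_dend_diameter`/`distal_dend_diameter`
#'   override it per group when not NA.
#' @slot n_dendrites total dendrite count (proximal + distal).
#' @slot dend_bend_angle bend of every dendrite away from the y axis (deg).
#' @slot dend_bifurcation_angle angle between sibling distal dendrites (deg).
#' @slot axon_bend_angle bend of the axon away from the -y axis (deg).
#' @slot axon_terminal_branch_angle fan angle spanned by terminal branches (deg).
#' @slot n_axon_terminals 1 = unbranched axon; >= 2 appends that many terminal
#'   branch sections (each `axon_terminal_length` x `axon_terminal_diameter`).
#' @slot removed_dendrites character vector of dendrite ids to delete
#'   (descendants are deleted with them).
#' @export
setClass("ArtificialNeuronParams",
  representation(
    soma_length = "numeric", soma_diameter = "numeric",
    axon_length = "numeric", axon_diameter = "numeric",
    proximal_dend_length = "numeric", distal_dend_length = "numeric",
    dend_diameter = "numeric",
    proximal_dend_diameter = "numeric", distal_dend_diameter = "numeric",
    n_dendrites = "integer",
    dend_bend_angle = "numeric", dend_bifurcation_angle = "numeric",
    axon_bend_angle = "numeric", axon_terminal_branch_angle = "numeric",
    n_axon_terminals = "integer",
    axon_terminal_length = "numeric", axon_terminal_diameter = "numeric",
    removed_dendrites = "character"
  )
)

setValidity("ArtificialNeuronParams", function(object) {
  pos <- c(
    "soma_length", "soma_diameter", "axon_length", "axon_diameter",
    "proximal_dend_length", "distal_dend_length", "dend_diameter",
    "axon_terminal_length", "axon_terminal_diameter"
  )
  for (f in pos) {
    v <- slot(object, f)
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      return(sprintf("parameter '%s' must be a single positive number", f))
    }
  }
  for (f in c("proximal_dend_diameter", "distal_dend_diameter")) {
    v <- slot(object, f)
    if (length(v) != 1L || (!is.na(v) && (!is.finite(v) || v <= 0))) {
      return(sprintf("parameter '%s' must be NA or a single positive number", f))
    }
  }
  ang <- c(
    "dend_bend_angle", "dend_bifurcation_angle", "axon_bend_angle",
    "axon_terminal_branch_angle"
  )
  for (f in ang) {
    v <- slot(object, f)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 90) {
      return(sprintf("parameter '%s' must be an angle in [0, 90] degrees", f))
    }
  }
  if (object@n_dendrites < 0L) return("parameter 'n_dendrites' must be >= 0")
  if (object@n_axon_terminals < 1L) return("parameter 'n_axon_terminals' must be >= 1")
  TRUE
})

#' Passive membrane and cytoplasm constants
#'
#' @slot cm specific membrane capacitance, uF/cm^2 (default 1).
#' @slot ra cytoplasmic (axial) resistivity, Ohm cm (default 80).
#' @slot rm specific membrane resistance, kOhm cm^2 (default 28); the leak
#'   conductance density is 1/rm.
#' @slot e_leak leak reversal potential, mV.
#' @export
setClass("PassiveParams",
  representation(cm = "numeric", ra = "numeric", rm = "numeric", e_leak = "numeric")
)

setValidity("PassiveParams", function(object) {
  for (f in c("cm", "ra", "rm")) {
    if (slot(object, f) <= 0) return(sprintf("'%s' must be positive", f))
  }
  if (!is.finite(object@e_leak)) return("'e_leak' must be finite")
  TRUE
})

#' Distance-dependent peak conductance density rule
#'
#' Peak density is `somatic + slope * dist/100um` on dendritic sections when
#' `dendritic_only` is TRUE (elsewhere the somatic value applies); channels
#' with slope 0 are uniform.
#'
#' @slot channel channel name ("na", "kdr", "ka", "h").
#' @slot somatic density at the soma, pS/um^2.
#' @slot slope pS/um^2 per 100 um of path distance from the soma midpoint.
#' @slot dendritic_only logical; whether the slope applies only to dendrites.
#' @export
setClass("ChannelDensityRule",
  representation(channel = "character", somatic = "numeric",
                 slope = "numeric", dendritic_only = "logical")
)

setValidity("ChannelDensityRule", function(object) {
  if (object@somatic < 0) return("somatic density must be >= 0")
  if (object@slope < 0) return("density slope must be >= 0")
  TRUE
})

#' Voltage-gated channel kinetic scheme
#'
#' A pluggable set of gating-variable definitions loaded from a structured
#' parameter file: per channel, a reversal potential and one or more gates,
#' each with a sigmoid steady-state curve and a constant or bell-shaped
#' voltage-dependent time constant.
#'
#' @slot name scheme name.
#' @slot version scheme version string.
#' @slot reversals named numeric, mV.
#' @slot channels named list; see [readKineticScheme()] for the layout.
#' @slot path source file path.
#' @slot hash md5 of the source file (provenance for logs/sidecars).
#' @export
setClass("KineticScheme",
  representation(name = "character", version = "character",
                 reversals = "numeric", channels = "list",
                 path = "character", hash = "character")
)

#' Full membrane description
#'
#' Bundles passive constants, per-channel density rules and the kinetic
#' scheme. With `passive_only = TRUE` all active conductances are dropped and
#' the membrane is a leaky RC cable.
#'
#' @slot passive a [PassiveParams-class] object.
#' @slot densities named list of [ChannelDensityRule-class] objects.
#' @slot kinetics a [KineticScheme-class] object.
#' @slot passive_only logical.
#' @export
setClass("Biophysics",
  representation(passive = "PassiveParams", densities = "list",
                 kinetics = "KineticScheme", passive_only = "logical")
)

#' Uniform extracellular field stimulus
#'
#' Positive amplitude places the anode on the dendritic (+y) side and the
#' cathode near the axon. The field is a step: on between `onset` and
#' `offset`, zero otherwise. `angle` is the angle between the field and the
#' y axis (carried for completeness; all shipped protocols use 0).
#'
#' @slot amplitude mV/mm, signed.
#' @slot angle degrees.
#' @slot onset,offset ms.
#' @export
setClass("FieldStimulus",
  representation(amplitude = "numeric", angle = "numeric",
                 onset = "numeric", offset = "numeric")
)

setValidity("FieldStimulus", function(object) {
  if (!is.finite(object@amplitude)) return("amplitude must be finite")
  if (object@offset <= object@onset) return("offset must be greater than onset")
  TRUE
})

#' Rectangular current injection (EPSC surrogate)
#'
#' A weak rectangular current pulse into one section, standing in for an
#' excitatory postsynaptic current. By default protocols place it on distal
#' dendrite "dend8" and span the field-on window.
#'
#' @slot target_section section id.
#' @slot arc_position fraction along the section in [0, 1].
#' @slot amplitude nA (>= 0, inward depolarizing).
#' @slot onset,duration ms.
#' @export
setClass("EPSCStimulus",
  representation(target_section = "character", arc_position = "numeric",
                 amplitude = "numeric", onset = "numeric", duration = "numeric")
)

setValidity("EPSCStimulus", function(object) {
  if (object@amplitude < 0) return("EPSC amplitude must be >= 0")
  if (object@duration <= 0) return("EPSC duration must be positive")
  TRUE
})

#' Solver configuration
#'
#' @slot dt time step, ms.
#' @slot max_dx maximum compartment length, um (each section gets an odd
#'   number of compartments so a true midpoint compartment exists).
#' @slot duration total simulated time, ms.
#' @slot record_sites data.frame(section, arc) of recording sites.
#' @slot steady_state_tolerance maximum |dV/dt| (mV/ms) accepted as settled.
#' @slot use_tables logical; evaluate gating rates through lookup tables
#'   (fast path) or exactly.
#' @export
setClass("SolverConfig",
  representation(dt = "numeric", max_dx = "numeric", duration = "numeric",
                 record_sites = "data.frame",
                 steady_state_tolerance = "numeric", use_tables = "logical")
)

setValidity("SolverConfig", function(object) {
  if (object@dt <= 0) return("dt must be positive")
  if (object@max_dx <= 0) return("max_dx must be positive")
  if (object@duration <= 0) return("duration must be positive")
  TRUE
})

#' Recorded voltage trace
#'
#' @slot times ms, strictly increasing.
#' @slot v matrix, one column per recorded site (mV, transmembrane).
#' @slot sites data.frame(section, arc, comp) describing the columns.
#' @slot vext named numeric or NULL-like empty numeric; per-site extracellular
#'   potential at unit field (mV per mV/mm).
#' @slot info list: stimulus and solver metadata.
#' @export
setClass("Trace",
  representation(times = "numeric", v = "matrix", sites = "data.frame",
                 vext = "numeric", info = "list"),
  prototype(vext = numeric(0), info = list())
)

setValidity("Trace", function(object) {
  if (length(object@times) != nrow(object@v)) return("times/v length mismatch")
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (ncol(object@v) != nrow(object@sites)) return("one site per voltage column required")
  TRUE
})

#' Detected spike train
#'
#' @slot spike_times ms.
#' @slot detection_threshold mV.
#' @slot refractory ms.
#' @export
setClass("SpikeTrain",
  representation(spike_times = "numeric", detection_threshold = "numeric",
                 refractory = "numeric")
)

setValidity("SpikeTrain", function(object) {
  st <- object@spike_times
  if (length(st) > 1 && any(diff(st) < object@refractory - 1e-9)) {
    return("inter-spike intervals must be >= refractory")
  }
  if (is.unsorted(st, strictly = TRUE) && length(st) > 1) {
    return("spike times must be strictly increasing")
  }
  TRUE
})

#' EF firing-threshold search result
#'
#' @slot polarity "+" or "-".
#' @slot e_threshold mV/mm, signed; NA when no spike occurred up to `e_max`.
#' @slot found logical.
#' @slot resolution mV/mm.
#' @slot bracket length-2 numeric (E without spike, E with spike), signed.
#' @slot search_log data.frame(E, n_spikes).
#' @export
setClass("ThresholdResult",
  representation(polarity = "character", e_threshold = "numeric",
                 found = "logical", resolution = "numeric",
                 bracket = "numeric", search_log = "data.frame")
)

#' Firing rate versus field curve
#'
#' @slot table data.frame(E, f) with f in Hz computed over the field-on window.
#' @slot window length-2 numeric, ms.
#' @export
setClass("FECurve", representation(table = "data.frame", window = "numeric"))

#' Morphology-parameter threshold sweep result
#'
#' @slot parameter swept parameter name.
#' @slot values list of parameter values.
#' @slot thresholds numeric, mV/mm (NA where no spike below e_max).
#' @slot polarity "+" or "-".
#' @slot fixed_context the base [ArtificialNeuronParams-class].
#' @export
setClass("SweepResult",
  representation(parameter = "character", values = "list",
                 thresholds = "numeric", polarity = "character",
                 fixed_context = "ArtificialNeuronParams")
)

#' Synthetic dendritic tree generator specification
#'
#' @slot n_branches number of dendritic sections to grow.
#' @slot branch_length_mean,branch_length_sd um.
#' @slot branch_diameter um.
#' @slot anode_side_fraction target fraction of dendritic cable on the +y
#'   (anode, for positive fields) side of the soma, in [0, 1].
#' @slot branching_depth maximum dendritic branching depth.
#' @slot seed integer RNG seed; generation is a pure function of (spec, seed).
#' @export
setClass("TreeGenSpec",
  representation(n_branches = "integer", branch_length_mean = "numeric",
                 branch_length_sd = "numeric", branch_diameter = "numeric",
                 anode_side_fraction = "numeric", branching_depth = "integer",
                 seed = "integer")
)

setValidity("TreeGenSpec", function(object) {
  if (object@n_branches < 0L) return("n_branches must be >= 0")
  if (object@branch_length_mean <= 0) return("branch_length_mean must be positive")
  if (object@branch_length_sd < 0) return("branch_length_sd must be >= 0")
  if (object@branch_diameter <= 0) return("branch_diameter must be positive")
  f <- object@anode_side_fraction
  if (!is.finite(f) || f < 0 || f > 1) return("anode_side_fraction must be in [0, 1]")
  if (object@branching_depth < 1L) return("branching_depth must be >= 1")
  TRUE
})
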