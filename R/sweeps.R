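## Morphology-parameter threshold sweeps and the monotonicity suite.

#' Sweep the EF firing threshold over a morphology parameter
#'
#' Rebuilds the artificial neuron for each value of one
#' [ArtificialNeuronParams-class] field (including the removal mask
#' `removed_dendrites`, for which `values` is a list of id vectors) and runs
#' [findEFThreshold()].
#'
#' @param base an [ArtificialNeuronParams-class]: the fixed context.
#' @param parameter field name to sweep.
#' @param values vector (or list, for `removed_dendrites`) of values.
#' @param polarity "+" or "-".
#' @param biophysics a [Biophysics-class].
#' @param e_max,resolution,coarse_step see [findEFThreshold()].
#' @param config a [SolverConfig-class].
#' @param onset,offset field window, ms.
#' @param epsc optional [EPSCStimulus-class] co-applied at every grid point.
#' @return A [SweepResult-class].
#' @export
sweepThreshold <- function(base = artificialNeuronParams(), parameter, values,
                           polarity = "+", biophysics = NULL,
                           e_max = 2000, resolution = 0.5, coarse_step = 10,
                           config = solverConfig(), onset = 100, offset = 600,
                           epsc = NULL) {
  if (!parameter %in% slotNames("ArtificialNeuronParams")) {
    stop("unknown parameter name: ", parameter)
  }
  if (is.null(biophysics)) biophysics <- .defaultBiophysics()
  if (!is.list(values)) values <- as.list(values)
  th <- vapply(values, function(v) {
    args <- list(params = base); args[[parameter]] <- v
    tree <- buildArtificialNeuron(do.call(updateParams, args))
    res <- findEFThreshold(tree, biophysics, polarity = polarity,
                           e_max = e_max, resolution = resolution,
                           coarse_step = coarse_step, config = config,
                           onset = onset, offset = offset, epsc = epsc)
    if (res@found) res@e_threshold else NA_real_
  }, numeric(1))
  new("SweepResult", parameter = parameter, values = values, thresholds = th,
      polarity = polarity, fixed_context = base)
}

#' Tidy view of a sweep result
#' @param x a [SweepResult-class].
#' @return data.frame(parameter, value, threshold).
#' @export
sweepToDataFrame <- function(x) {
  val <- vapply(x@values, function(v) paste(format(v), collapse = "+"), character(1))
  val[val == ""] <- "none"
  data.frame(parameter = x@parameter, value = val, threshold = x@thresholds)
}

setMethod("show", "SweepResult", function(object) {
  cat("SweepResult over '", object@parameter, "' (polarity ",
      object@polarity, ")\n", sep = "")
  print(sweepToDataFrame(object), row.names = FALSE)
})

## direction of a threshold series, at the search resolution
.sweepDirection <- function(th, resolution) {
  if (anyNA(th)) return("none-found")
  d <- diff(abs(th))
  total <- abs(th[length(th)]) - abs(th[1])
  if (all(d >= -resolution) && total > resolution) return("increasing")
  if (all(d <= resolution) && total < -resolution) return("decreasing")
  if (all(abs(d) <= resolution)) return("flat")
  "non-monotonic"
}

#' The catalogue of morphology-threshold relationships
#'
#' One row per qualitative relationship between a morphology parameter and
#' the EF firing threshold, with the desk-scale grid used by
#' [monotonicitySuite()] and the expected direction of the threshold as the
#' parameter increases. Grids span the ranges explored per parameter; the
#' dendrite-structure sweeps use 2 um dendrites (diameter) as in the
#' corresponding experiments, and the terminal-angle sweep uses a branched
#' (two-terminal) axon so the angle exists.
#'
#' @return data.frame(relationship, parameter, expected) with grid and base
#'   modifications in attributes "values" and "base_mods" (lists keyed by
#'   relationship).
#' @export
thresholdRelationships <- function() {
  rel <- list(
    soma_diameter = list(parameter = "soma_diameter",
                         values = c(5, 10, 15, 20), expected = "decreasing"),
    axon_diameter = list(parameter = "axon_diameter",
                         values = c(1, 2, 3, 4), expected = "increasing"),
    proximal_dend_diameter = list(parameter = "proximal_dend_diameter",
                                  values = c(0.5, 1, 2, 3), expected = "decreasing"),
    distal_dend_diameter = list(parameter = "distal_dend_diameter",
                                values = c(0.5, 1, 2, 3), expected = "decreasing"),
    soma_length = list(parameter = "soma_length",
                       values = c(5, 10, 20, 30), expected = "decreasing"),
    axon_length = list(parameter = "axon_length",
                       values = c(30, 50, 80, 120), expected = "decreasing"),
    proximal_dend_length = list(parameter = "proximal_dend_length",
                                values = c(4, 8, 16, 24), expected = "decreasing"),
    distal_dend_length = list(parameter = "distal_dend_length",
                              values = c(1, 2, 6, 10), expected = "decreasing"),
    dend_bend_angle = list(parameter = "dend_bend_angle",
                           values = c(0, 30, 60, 90), expected = "increasing",
                           base_mods = list(dend_diameter = 2, distal_dend_length = 8)),
    dend_bifurcation_angle = list(parameter = "dend_bifurcation_angle",
                                  values = c(0, 30, 60, 90), expected = "increasing",
                                  base_mods = list(dend_diameter = 2, distal_dend_length = 8)),
    n_dendrites = list(parameter = "n_dendrites",
                       values = c(3, 6, 9, 12), expected = "decreasing",
                       base_mods = list(dend_diameter = 2, distal_dend_length = 8)),
    dendrite_removal = list(parameter = "removed_dendrites",
                            values = list(character(0), "dend12",
                                          c("dend11", "dend12"),
                                          c("dend9", "dend10", "dend11", "dend12")),
                            expected = "increasing"),
    axon_bend_angle = list(parameter = "axon_bend_angle",
                           values = c(0, 30, 60, 90), expected = "decreasing"),
    axon_terminal_branch_angle = list(parameter = "axon_terminal_branch_angle",
                                      values = c(0, 30, 60, 90),
                                      expected = "decreasing",
                                      base_mods = list(n_axon_terminals = 2L)),
    n_axon_terminals = list(parameter = "n_axon_terminals",
                            values = c(1L, 2L, 3L, 4L), expected = "increasing")
  )
  out <- data.frame(
    relationship = names(rel),
    parameter = vapply(rel, `[[`, character(1), "parameter"),
    expected = vapply(rel, `[[`, character(1), "expected"),
    row.names = NULL
  )
  attr(out, "values") <- lapply(rel, `[[`, "values")
  attr(out, "base_mods") <- lapply(rel, function(r) r$base_mods %||% list())
  out
}

#' Run the morphology-threshold monotonicity suite
#'
#' For every relationship in [thresholdRelationships()] (or a subset), sweeps
#' the threshold over the declared grid and compares the observed direction
#' with the expected one.
#'
#' @param relationships optional character vector of relationship names.
#' @param base base [ArtificialNeuronParams-class].
#' @param biophysics a [Biophysics-class].
#' @param polarity "+" or "-".
#' @param e_max,resolution,coarse_step search settings (the default coarse
#'   step of 25 mV/mm keeps the suite at desk scale; bisection still reaches
#'   `resolution`).
#' @param config a [SolverConfig-class].
#' @return data.frame(relationship, parameter, expected, observed, pass) with
#'   the full sweeps in attribute "sweeps".
#' @export
monotonicitySuite <- function(relationships = NULL,
                              base = artificialNeuronParams(),
                              biophysics = NULL, polarity = "+",
                              e_max = 2000, resolution = 0.5,
                              coarse_step = 25, config = solverConfig()) {
  if (is.null(biophysics)) biophysics <- .defaultBiophysics()
  cat_rel <- thresholdRelationships()
  if (!is.null(relationships)) {
    keep <- cat_rel$relationship %in% relationships
    miss <- setdiff(relationships, cat_rel$relationship)
    if (length(miss)) stop("unknown relationship(s): ", paste(miss, collapse = ", "))
    cat_rel <- cat_rel[keep, , drop = FALSE]
  }
  values <- attr(thresholdRelationships(), "values")
  mods <- attr(thresholdRelationships(), "base_mods")
  sweeps <- list()
  observed <- character(nrow(cat_rel))
  for (i in seq_len(nrow(cat_rel))) {
    nm <- cat_rel$relationship[i]
    b <- base
    if (length(mods[[nm]])) b <- do.call(updateParams, c(list(params = b), mods[[nm]]))
    sw <- sweepThreshold(b, cat_rel$parameter[i], values[[nm]],
                         polarity = polarity, biophysics = biophysics,
                         e_max = e_max, resolution = resolution,
                         coarse_step = coarse_step, config = config)
    sweeps[[nm]] <- sw
    observed[i] <- .sweepDirection(sw@thresholds, resolution)
  }
  out <- data.frame(cat_rel, observed = observed,
                    pass = observed == cat_rel$expected)
  attr(out, "sweeps") <- sweeps
  out
}

#' EPSC amplitude ordering of EF thresholds
#'
#' Thresholds with rectangular EPSC pulses of increasing amplitude into the
#' distal dendrite "dend8", optionally across several axon lengths.
#'
#' @param amplitudes nA.
#' @param axon_lengths um.
#' @param base base [ArtificialNeuronParams-class].
#' @param biophysics a [Biophysics-class].
#' @param polarity,e_max,resolution,coarse_step,config,onset,offset as in
#'   [findEFThreshold()].
#' @return data.frame(axon_length, amplitude, threshold).
#' @export
epscThresholdOrdering <- function(amplitudes = c(0, 0.01, 0.03),
                                  axon_lengths = 50,
                                  base = artificialNeuronParams(),
                                  biophysics = NULL, polarity = "+",
                                  e_max = 2000, resolution = 0.5,
                                  coarse_step = 10, config = solverConfig(),
                                  onset = 100, offset = 600) {
  if (is.null(biophysics)) biophysics <- .defaultBiophysics()
  rows <- list()
  for (L in axon_lengths) {
    tree <- buildArtificialNeuron(updateParams(base, axon_length = L))
    system <- compartmentalize(tree, biophysics, max_dx = config@max_dx)
    init <- initSteadyState(system, config)
    for (a in amplitudes) {
      res <- if (a == 0) {
        findEFThreshold(system, polarity = polarity, e_max = e_max,
                        resolution = resolution, coarse_step = coarse_step,
                        config = config, onset = onset, offset = offset,
                        init = init)
      } else {
        tryCatch(
          thresholdWithEPSC(system,
                            epsc = epscStimulus(amplitude = a, onset = onset,
                                                duration = offset - onset),
                            polarity = polarity, e_max = e_max,
                            resolution = resolution, coarse_step = coarse_step,
                            config = config, onset = onset, offset = offset,
                            init = init),
          error = function(e) {
            if (grepl("EPSC alone evokes a spike", conditionMessage(e))) NULL
            else stop(e)
          })
      }
      rows[[length(rows) + 1L]] <- data.frame(
        axon_length = L, amplitude = a,
        threshold = if (!is.null(res) && res@found) res@e_threshold else NA_real_,
        epsc_alone_spikes = is.null(res))
    }
  }
  do.call(rbind, rows)
}
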