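## Configuration-driven experiment runner: one structured config file (or
## list) in, a result bundle (tidy CSV + resolved-config JSON sidecar + log)
## out. Everything is deterministic, so a bundle is reproducible bit for bit
## from its sidecar.

.wbProtocols <- c("build", "simulate", "threshold", "sweep", "fe_curve",
                  "polarize", "generate_tree", "reproduce_figures")

## validate the config skeleton before any computation, naming offending keys
.validateRunConfig <- function(config) {
  if (!is.list(config)) stop("config must be a list (or a YAML file path)")
  if (is.null(config$protocol)) stop("config validation: missing key 'protocol'")
  if (!config$protocol %in% .wbProtocols) {
    stop("config validation: unknown protocol '", config$protocol, "'")
  }
  if (is.null(config$outdir)) stop("config validation: missing key 'outdir'")
  m <- config$morphology
  if (config$protocol %in% c("simulate", "threshold", "fe_curve", "polarize", "build")) {
    if (is.null(m) || is.null(m$type)) {
      stop("config validation: missing key 'morphology$type'")
    }
    if (!m$type %in% c("artificial", "swc", "generated")) {
      stop("config validation: morphology$type must be artificial, swc or generated")
    }
    if (m$type == "swc" && (is.null(m$path) || !file.exists(m$path))) {
      stop("config validation: morphology$path missing or unresolvable")
    }
    if (m$type == "artificial" && !is.null(m$params)) {
      known <- slotNames("ArtificialNeuronParams")
      bad <- setdiff(names(m$params), known)
      if (length(bad)) {
        stop("config validation: unknown morphology parameter(s): ",
             paste(bad, collapse = ", "))
      }
      for (nm in names(m$params)) {
        v <- m$params[[nm]]
        if (is.numeric(v) && nm %in% c("soma_length", "soma_diameter",
                                       "axon_length", "axon_diameter",
                                       "proximal_dend_length", "distal_dend_length",
                                       "dend_diameter") && v <= 0) {
          stop("config validation: morphology parameter '", nm,
               "' must be positive")
        }
      }
    }
  }
  invisible(TRUE)
}

.wbMorphology <- function(config) {
  m <- config$morphology
  switch(m$type,
    artificial = {
      p <- do.call(artificialNeuronParams, m$params %||% list())
      buildArtificialNeuron(p)
    },
    swc = readSWC(m$path),
    generated = generateTree(do.call(treeGenSpec, m$spec %||% list()))
  )
}

.wbBiophysics <- function(config) {
  b <- config[["biophysics"]] %||% list()
  pas <- do.call(passiveParams, b[["passive"]] %||% list())
  if (isTRUE(b[["passive_only"]])) return(passiveBiophysics(pas))
  kin <- if (is.null(b[["kinetics"]]) || identical(b[["kinetics"]], "default")) {
    defaultKineticScheme()
  } else readKineticScheme(b[["kinetics"]])
  biophysics(passive = pas, kinetics = kin)
}

.wbSolverConfig <- function(config) {
  do.call(solverConfig, config$solver %||% list())
}

#' Run a configured experiment
#'
#' Validates the configuration (reporting offending keys before any
#' simulation starts), executes the named protocol, and writes a result
#' bundle to the output directory: `result.csv`, a `config.json` sidecar
#' with the fully resolved configuration (morphology parameters, kinetics
#' file hash, solver settings, package version, seed), and `log.txt`.
#'
#' @param config a list, or the path to a YAML config file, with keys
#'   `protocol` (one of build, simulate, threshold, sweep, fe_curve,
#'   polarize, generate_tree, reproduce_figures), `morphology`
#'   (`type`: artificial/swc/generated plus `params`/`path`/`spec`),
#'   `biophysics`, `solver`, `settings` (protocol-specific), `outdir`,
#'   and optionally `seed`.
#' @return Invisibly, a list with the protocol result, the bundle paths and
#'   the resolved config.
#' @export
runExperiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validateRunConfig(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logline("cableEF %s | protocol: %s | %s", as.character(packageVersion("cableEF")),
          config$protocol, format(Sys.time(), "%Y-%m-%d %H:%M:%S"))

  set <- config$settings %||% list()
  bio <- .wbBiophysics(config)
  cfg <- .wbSolverConfig(config)
  logline("kinetics: %s (md5 %s)", bio@kinetics@name, bio@kinetics@hash)
  if (!is.null(config$seed)) logline("seed: %d", as.integer(config$seed))

  result <- switch(config$protocol,
    build = {
      tree <- .wbMorphology(config)
      writeSWC(tree, file.path(outdir, "morphology.swc"))
      sections(tree)
    },
    simulate = {
      tree <- .wbMorphology(config)
      tr <- simulate(tree, bio,
                     field = fieldStimulus(set$E %||% 0,
                                           onset = set$onset %||% 100,
                                           offset = set$offset %||% 600),
                     config = cfg)
      traceToDataFrame(tr)
    },
    threshold = {
      tree <- .wbMorphology(config)
      res <- findEFThreshold(tree, bio,
                             polarity = set$polarity %||% "+",
                             e_max = set$e_max %||% 2000,
                             resolution = set$resolution %||% 0.5,
                             coarse_step = set$coarse_step %||% 10,
                             config = cfg,
                             onset = set$onset %||% 100,
                             offset = set$offset %||% 600)
      logline("threshold found: %s", res@found)
      data.frame(polarity = res@polarity, e_threshold = res@e_threshold,
                 found = res@found, resolution = res@resolution,
                 bracket_lo = res@bracket[1], bracket_hi = res@bracket[2],
                 n_simulations = nrow(res@search_log))
    },
    sweep = {
      base <- do.call(artificialNeuronParams,
                      (config$morphology$params %||% list()))
      sw <- sweepThreshold(base, set$parameter, set$values,
                           polarity = set$polarity %||% "+",
                           biophysics = bio,
                           e_max = set$e_max %||% 2000,
                           resolution = set$resolution %||% 0.5,
                           coarse_step = set$coarse_step %||% 25,
                           config = cfg)
      sweepToDataFrame(sw)
    },
    fe_curve = {
      tree <- .wbMorphology(config)
      fe <- fECurve(tree, bio, e_grid = unlist(set$e_grid),
                    config = cfg, onset = set$onset %||% 100,
                    offset = set$offset %||% 600)
      fe@table
    },
    polarize = {
      tree <- .wbMorphology(config)
      pol <- polarizationVsE(tree, bio, e_grid = unlist(set$e_grid %||% list(-50, -25, 25, 50)),
                             config = cfg)
      logline("soma polarization slope: %.6g mV per mV/mm", pol$slope)
      pol$table
    },
    generate_tree = {
      tree <- generateTree(do.call(treeGenSpec, config$morphology$spec %||% list()))
      writeSWC(tree, file.path(outdir, "generated.swc"))
      data.frame(n_sections = nSections(tree),
                 asymmetry_index = asymmetryIndex(tree),
                 total_dendritic_length = totalDendriticLength(tree))
    },
    reproduce_figures = reproduceFigures(outdir, biophysics = bio,
                                         config = cfg, settings = set)
  )

  result_path <- file.path(outdir, "result.csv")
  write.csv(result, result_path, row.names = FALSE)
  resolved <- config
  resolved$package_version <- as.character(packageVersion("cableEF"))
  resolved$kinetics_hash <- bio@kinetics@hash
  resolved$solver <- list(dt = cfg@dt, max_dx = cfg@max_dx,
                          duration = cfg@duration)
  sidecar <- file.path(outdir, "config.json")
  jsonlite::write_json(resolved, sidecar, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  logline("wrote %s", result_path)
  invisible(list(result = result, paths = list(result = result_path,
                                               sidecar = sidecar, log = logf),
                 config = resolved))
}

#' Reproduce the package's figure-style experiments
#'
#' Runs, at desk-scale grids: the f-E curve of the reference artificial
#' neuron, the full morphology-threshold monotonicity suite, the EPSC
#' threshold-ordering experiment, and the somatic polarization slopes of
#' three synthetic asymmetry archetypes (anode-heavy, radial/symmetric,
#' cathode-heavy). Writes one CSV per experiment plus a monotonicity summary.
#'
#' @param outdir output directory.
#' @param biophysics a [Biophysics-class].
#' @param config a [SolverConfig-class].
#' @param settings list; supports `resolution`, `coarse_step`, `e_max`,
#'   `seed`.
#' @return The monotonicity summary data.frame.
#' @export
reproduceFigures <- function(outdir, biophysics = NULL,
                             config = solverConfig(), settings = list()) {
  if (is.null(biophysics)) biophysics <- .defaultBiophysics()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- settings$resolution %||% 0.5
  cs <- settings$coarse_step %||% 25
  emax <- settings$e_max %||% 2000
  seed <- settings$seed %||% 1L

  tree <- buildArtificialNeuron()
  system <- compartmentalize(tree, biophysics, max_dx = config@max_dx)
  init <- initSteadyState(system, config)

  ## f-E curve around the two thresholds
  thp <- findEFThreshold(system, polarity = "+", e_max = emax,
                         resolution = res, coarse_step = cs, config = config,
                         init = init)
  thn <- findEFThreshold(system, polarity = "-", e_max = emax,
                         resolution = res, coarse_step = cs, config = config,
                         init = init)
  grids <- c()
  if (thp@found) grids <- c(grids, seq(thp@e_threshold - 5, thp@e_threshold + 30, by = 5))
  if (thn@found) grids <- c(grids, seq(thn@e_threshold - 30, thn@e_threshold + 5, by = 5))
  fe <- fECurve(system, e_grid = grids, config = config, init = init)
  write.csv(fe@table, file.path(outdir, "fe_curve.csv"), row.names = FALSE)

  ## monotonicity suite
  mono <- monotonicitySuite(biophysics = biophysics, e_max = emax,
                            resolution = res, coarse_step = cs,
                            config = config)
  sweeps <- attr(mono, "sweeps")
  for (nm in names(sweeps)) {
    write.csv(sweepToDataFrame(sweeps[[nm]]),
              file.path(outdir, paste0("sweep_", nm, ".csv")),
              row.names = FALSE)
  }
  write.csv(mono, file.path(outdir, "monotonicity_summary.csv"),
            row.names = FALSE)

  ## EPSC ordering
  ep <- epscThresholdOrdering(biophysics = biophysics, e_max = emax,
                              resolution = res, coarse_step = cs,
                              config = config)
  write.csv(ep, file.path(outdir, "epsc_thresholds.csv"), row.names = FALSE)

  ## polarization slopes of synthetic asymmetry archetypes
  pas <- passiveBiophysics(biophysics@passive)
  arch <- data.frame(archetype = c("anode_heavy", "radial", "cathode_heavy"),
                     fraction = c(0.85, 0.5, 0.2))
  slopes <- vapply(seq_len(nrow(arch)), function(i) {
    tr <- generateTree(treeGenSpec(anode_side_fraction = arch$fraction[i],
                                   seed = seed + i))
    polarizationVsE(tr, pas, e_grid = c(-50, -25, 25, 50), config = config)$slope
  }, numeric(1))
  arch$soma_polarization_slope <- slopes
  write.csv(arch, file.path(outdir, "polarization_slopes.csv"), row.names = FALSE)

  mono
}
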