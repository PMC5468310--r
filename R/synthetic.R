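## Seeded generation of synthetic dendritic trees with controlled
## anode/cathode-side cable asymmetry. These stand in for reconstructed
## morphologies when studying how dendritic asymmetry sets the sign of the
## field-induced somatic polarization: they are synthetic archetypes, not
## reconstructions.

#' Specification for a synthetic asymmetric dendritic tree
#'
#' @param n_branches dendritic section count (default 16).
#' @param branch_length_mean,branch_length_sd um (defaults 60 and 20).
#' @param branch_diameter um (default 1).
#' @param anode_side_fraction target fraction of dendritic cable on the +y
#'   side of the soma.
#' @param branching_depth maximum branching depth (default 3).
#' @param seed RNG seed.
#' @return A [TreeGenSpec-class].
#' @export
treeGenSpec <- function(n_branches = 16L, branch_length_mean = 60,
                        branch_length_sd = 20, branch_diameter = 1,
                        anode_side_fraction = 0.5, branching_depth = 3L,
                        seed = 1L) {
  new("TreeGenSpec", n_branches = as.integer(n_branches),
      branch_length_mean = branch_length_mean,
      branch_length_sd = branch_length_sd,
      branch_diameter = branch_diameter,
      anode_side_fraction = anode_side_fraction,
      branching_depth = as.integer(branching_depth),
      seed = as.integer(seed))
}

## evaluate expr under a local RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic dendritic tree
#'
#' Grows `n_branches` dendritic sections from a 10 x 10 um soma (plus a
#' 50 x 2 um axon toward -y), assigning each branch to the +y or -y side
#' greedily so the realized side fractions track the target, then rescales
#' the +y-side branch lengths once so the realized anode-side cable fraction
#' matches `anode_side_fraction` (always within 0.05, usually exactly).
#' Branch directions stay within 60 degrees of the vertical on their side,
#' so every section's center is on its assigned side of the soma midpoint.
#' Generation is a pure function of the spec (including its seed).
#'
#' @param spec a [TreeGenSpec-class].
#' @return A [MorphologyTree-class].
#' @export
generateTree <- function(spec) {
  validObject(spec)
  .withSeed(spec@seed, .generateTreeImpl(spec))
}

.generateTreeImpl <- function(spec) {
  n <- spec@n_branches
  rows <- list(
    .sectionRow("soma", "soma", c(0, -5), c(0, 5), 10),
    .sectionRow("axon", "axon", c(0, -5), c(0, -55), 2,
                parent = "soma", attach_end = "proximal")
  )
  if (n == 0L) {
    tree <- new("MorphologyTree", sections = do.call(rbind, rows),
                metadata = list(spec = spec))
    validObject(tree)
    return(tree)
  }
  target <- spec@anode_side_fraction
  ## branch plan: side, parent, tilt from the vertical on its side, length
  side <- integer(n)        # +1 up, -1 down
  parent <- character(n)
  depth <- integer(n)
  tilt <- numeric(n)
  len <- numeric(n)
  id <- paste0("syn", seq_len(n))
  up_len <- 0; down_len <- 0
  for (i in seq_len(n)) {
    len[i] <- max(2, rnorm(1, spec@branch_length_mean, spec@branch_length_sd))
    tilt[i] <- runif(1, -60, 60)
    frac_if_up <- (up_len + len[i]) / (up_len + down_len + len[i])
    frac_if_down <- up_len / (up_len + down_len + len[i])
    side[i] <- if (abs(frac_if_up - target) <= abs(frac_if_down - target)) 1L else -1L
    cand <- which(side[seq_len(i - 1L)] == side[i] & depth[seq_len(i - 1L)] < spec@branching_depth)
    parent[i] <- if (length(cand)) {
      pick <- cand[sample.int(length(cand), 1L)]
      depth[i] <- depth[pick] + 1L
      id[pick]
    } else {
      depth[i] <- 1L
      "soma"
    }
    if (side[i] > 0) up_len <- up_len + len[i] else down_len <- down_len + len[i]
  }
  ## one-shot rescale of the up side to hit the target cable fraction
  if (up_len > 0 && down_len > 0 && target > 0 && target < 1) {
    cfac <- target * down_len / ((1 - target) * up_len)
    len[side > 0] <- len[side > 0] * cfac
  }
  ## realize coordinates (parents precede children by construction)
  p_of <- setNames(seq_len(n), id)
  tip <- list()
  for (i in seq_len(n)) {
    if (parent[i] == "soma") {
      start <- if (side[i] > 0) c(0, 5) else c(0, -5)
      attach <- if (side[i] > 0) "distal" else "proximal"
      kind <- "dend_proximal"
    } else {
      start <- tip[[parent[i]]]
      attach <- "distal"
      kind <- "dend_distal"
    }
    dir <- c(sin(deg2rad(tilt[i])), side[i] * cos(deg2rad(tilt[i])))
    tip[[id[i]]] <- start + len[i] * dir
    rows[[length(rows) + 1L]] <- .sectionRow(id[i], kind, start, tip[[id[i]]],
                                             spec@branch_diameter,
                                             parent = parent[i],
                                             attach_end = attach)
  }
  tree <- new("MorphologyTree", sections = do.call(rbind, rows),
              metadata = list(spec = spec, seed = spec@seed))
  validObject(tree)
  realized <- asymmetryIndex(tree)
  if (abs(realized - target) > 0.05) {
    stop(sprintf("infeasible generator spec: realized anode-side fraction %.3f, target %.3f",
                 realized, target))
  }
  tree
}

#' Anode-side dendritic asymmetry index
#'
#' The fraction of total dendritic cable length whose section center lies
#' above (+y side of) the soma midpoint.
#'
#' @param tree a [MorphologyTree-class].
#' @return Fraction in [0, 1].
#' @export
asymmetryIndex <- function(tree) {
  s <- tree@sections
  root <- which(is.na(s$parent))
  soma_y <- (s$y0[root] + s$y1[root]) / 2
  dend <- s$kind %in% c("dend_proximal", "dend_distal")
  if (!any(dend)) stop("asymmetry index undefined: morphology has no dendrites")
  len <- sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2)[dend]
  cy <- ((s$y0 + s$y1) / 2)[dend]
  sum(len[cy > soma_y]) / sum(len)
}

#' Mirror a morphology about the x axis
#'
#' Utility for asymmetry analyses: reflects all coordinates through y = soma
#' midpoint level (soma centered trees reflect about the x axis).
#'
#' @param tree a [MorphologyTree-class].
#' @return The mirrored tree.
#' @export
mirrorTree <- function(tree) {
  s <- tree@sections
  s$y0 <- -s$y0; s$y1 <- -s$y1
  ## a mirrored cylinder keeps its proximal/distal identity
  tree@sections <- s
  validObject(tree)
  tree
}
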