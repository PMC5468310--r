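## Construction and manipulation of branched neuron geometry.

deg2rad <- function(a) a * pi / 180

## unit vector at `angle` degrees away from the +y axis, rotating toward +x
## for positive angles
.dirFromY <- function(angle_deg) {
  a <- deg2rad(angle_deg)
  c(sin(a), cos(a))
}

## rotate a 2-vector by `angle` degrees (counter-clockwise)
.rot2 <- function(v, angle_deg) {
  a <- deg2rad(angle_deg)
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}

.sectionRow <- function(id, kind, p, d, diam, parent = NA_character_,
                        attach_end = NA_character_) {
  data.frame(id = id, kind = kind, x0 = p[1], y0 = p[2], x1 = d[1], y1 = d[2],
             diam = diam, parent = parent, attach_end = attach_end,
             stringsAsFactors = FALSE)
}

#' Create parameters for the artificial neuron
#'
#' All arguments default to the reference morphology; see
#' [ArtificialNeuronParams-class] for meanings and units.
#'
#' @param soma_length,soma_diameter,axon_length,axon_diameter um.
#' @param proximal_dend_length,distal_dend_length,dend_diameter um.
#' @param proximal_dend_diameter,distal_dend_diameter um; NA means use
#'   `dend_diameter`.
#' @param n_dendrites total dendrite count.
#' @param dend_bend_angle,dend_bifurcation_angle,axon_bend_angle,axon_terminal_branch_angle degrees.
#' @param n_axon_terminals terminal branch count (1 = unbranched axon).
#' @param axon_terminal_length,axon_terminal_diameter um.
#' @param removed_dendrites character vector of dendrite ids.
#' @return An [ArtificialNeuronParams-class] object.
#' @examples
#' p <- artificialNeuronParams()
#' tree <- buildArtificialNeuron(p)
#' nSections(tree)
#' @export
artificialNeuronParams <- function(soma_length = 10, soma_diameter = 10,
                                   axon_length = 50, axon_diameter = 2,
                                   proximal_dend_length = 8,
                                   distal_dend_length = 2,
                                   dend_diameter = 1,
                                   proximal_dend_diameter = NA_real_,
                                   distal_dend_diameter = NA_real_,
                                   n_dendrites = 12L,
                                   dend_bend_angle = 0,
                                   dend_bifurcation_angle = 0,
                                   axon_bend_angle = 0,
                                   axon_terminal_branch_angle = 0,
                                   n_axon_terminals = 1L,
                                   axon_terminal_length = 20,
                                   axon_terminal_diameter = 2,
                                   removed_dendrites = character(0)) {
  new("ArtificialNeuronParams",
      soma_length = soma_length, soma_diameter = soma_diameter,
      axon_length = axon_length, axon_diameter = axon_diameter,
      proximal_dend_length = proximal_dend_length,
      distal_dend_length = distal_dend_length,
      dend_diameter = dend_diameter,
      proximal_dend_diameter = as.numeric(proximal_dend_diameter),
      distal_dend_diameter = as.numeric(distal_dend_diameter),
      n_dendrites = as.integer(n_dendrites),
      dend_bend_angle = dend_bend_angle,
      dend_bifurcation_angle = dend_bifurcation_angle,
      axon_bend_angle = axon_bend_angle,
      axon_terminal_branch_angle = axon_terminal_branch_angle,
      n_axon_terminals = as.integer(n_axon_terminals),
      axon_terminal_length = axon_terminal_length,
      axon_terminal_diameter = axon_terminal_diameter,
      removed_dendrites = removed_dendrites)
}

#' Update selected fields of an ArtificialNeuronParams object
#'
#' @param params an [ArtificialNeuronParams-class] object.
#' @param ... named fields to replace.
#' @return The updated object (re-validated).
#' @export
updateParams <- function(params, ...) {
  mods <- list(...)
  bad <- setdiff(names(mods), slotNames("ArtificialNeuronParams"))
  if (length(bad)) stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  for (nm in names(mods)) {
    v <- mods[[nm]]
    if (nm %in% c("n_dendrites", "n_axon_terminals")) v <- as.integer(v)
    if (nm == "removed_dendrites") v <- as.character(v)
    slot(params, nm) <- v
  }
  validObject(params)
  params
}

#' Build the artificial pyramidal-like neuron
#'
#' The soma is centered at the origin with its axis along y; the axon extends
#' toward -y from the soma's proximal (bottom) end; dendrites extend toward
#' +y from the soma's distal (top) end. Proximal dendrites are numbered
#' `dend1..dendK` left to right; distal dendrites `dend(K+1)..dendN` are
#' assigned round-robin to proximal parents (so with the default 4 proximal /
#' 8 distal layout, "dend8" is the first distal branch of the rightmost
#' proximal dendrite). Proximal dendrites fan symmetrically about +y at 10
#' degree spacing; the dendrite bend angle rotates each dendrite further away
#' from the y axis, and the bifurcation angle splits sibling distal dendrites
#' symmetrically about the parent axis.
#'
#' @param params an [ArtificialNeuronParams-class] object.
#' @return A valid [MorphologyTree-class]; building is a pure function of
#'   `params`.
#' @export
buildArtificialNeuron <- function(params = artificialNeuronParams()) {
  validObject(params)
  p <- params
  half <- p@soma_length / 2
  soma_top <- c(0, half)
  soma_bot <- c(0, -half)
  rows <- list(.sectionRow("soma", "soma", soma_bot, soma_top, p@soma_diameter))

  ## axon toward -y, bent by axon_bend_angle away from the -y axis (toward +x)
  axon_dir <- .rot2(c(0, -1), p@axon_bend_angle)
  rows[[length(rows) + 1L]] <- .sectionRow(
    "axon", "axon", soma_bot, soma_bot + p@axon_length * axon_dir,
    p@axon_diameter, parent = "soma", attach_end = "proximal")

  ## axon terminal branches (n_axon_terminals == 1 means the bare axon tip)
  if (p@n_axon_terminals >= 2L) {
    tip <- soma_bot + p@axon_length * axon_dir
    spread <- p@axon_terminal_branch_angle
    offs <- seq(-spread / 2, spread / 2, length.out = p@n_axon_terminals)
    for (t in seq_len(p@n_axon_terminals)) {
      dir_t <- .rot2(axon_dir, offs[t])
      rows[[length(rows) + 1L]] <- .sectionRow(
        paste0("term", t), "axon_terminal", tip,
        tip + p@axon_terminal_length * dir_t,
        p@axon_terminal_diameter, parent = "axon", attach_end = "distal")
    }
  }

  ## dendrites
  nd <- p@n_dendrites
  if (nd > 0L) {
    n_prox <- max(1L, as.integer(round(nd / 3)))
    n_prox <- min(n_prox, nd)
    n_dist <- nd - n_prox
    d_prox <- if (is.na(p@proximal_dend_diameter)) p@dend_diameter else p@proximal_dend_diameter
    d_dist <- if (is.na(p@distal_dend_diameter)) p@dend_diameter else p@distal_dend_diameter

    ## symmetric fan about +y at 10 degree spacing, left to right
    base_ang <- (seq_len(n_prox) - (n_prox + 1) / 2) * 10
    away <- ifelse(base_ang > 0, 1, ifelse(base_ang < 0, -1, 1))
    prox_ang <- base_ang + away * p@dend_bend_angle
    prox_dir <- lapply(prox_ang, .dirFromY)
    prox_tip <- vector("list", n_prox)
    for (i in seq_len(n_prox)) {
      prox_tip[[i]] <- soma_top + p@proximal_dend_length * prox_dir[[i]]
      rows[[length(rows) + 1L]] <- .sectionRow(
        paste0("dend", i), "dend_proximal", soma_top, prox_tip[[i]],
        d_prox, parent = "soma", attach_end = "distal")
    }

    if (n_dist > 0L) {
      parent_of <- ((seq_len(n_dist) - 1L) %% n_prox) + 1L
      for (par in seq_len(n_prox)) {
        kids <- which(parent_of == par)
        nc <- length(kids)
        if (nc == 0L) next
        offs <- if (nc == 1L) 0 else seq(-p@dend_bifurcation_angle / 2,
                                         p@dend_bifurcation_angle / 2,
                                         length.out = nc)
        for (k in seq_len(nc)) {
          num <- n_prox + kids[k]
          dir_k <- .rot2(prox_dir[[par]], -offs[k]) # -: +off rotates toward +x
          rows[[length(rows) + 1L]] <- .sectionRow(
            paste0("dend", num), "dend_distal", prox_tip[[par]],
            prox_tip[[par]] + p@distal_dend_length * dir_k,
            d_dist, parent = paste0("dend", par), attach_end = "distal")
        }
      }
    }
  }

  s <- do.call(rbind, rows)
  tree <- new("MorphologyTree", sections = s,
              metadata = list(params = params))
  if (length(p@removed_dendrites)) {
    tree <- removeSections(tree, p@removed_dendrites)
  }
  validObject(tree)
  tree
}

#' Remove sections (and their descendants) from a morphology
#'
#' @param tree a [MorphologyTree-class].
#' @param ids character vector of section ids.
#' @return The pruned tree.
#' @export
removeSections <- function(tree, ids) {
  s <- tree@sections
  missing <- setdiff(ids, s$id)
  if (length(missing)) stop("unknown section id(s): ", paste(missing, collapse = ", "))
  if ("soma" %in% ids || any(is.na(s$parent[s$id %in% ids]) )) {
    stop("cannot remove the soma")
  }
  drop <- ids
  repeat {
    more <- s$id[s$parent %in% drop & !(s$id %in% drop)]
    if (!length(more)) break
    drop <- c(drop, more)
  }
  tree@sections <- s[!(s$id %in% drop), , drop = FALSE]
  rownames(tree@sections) <- NULL
  validObject(tree)
  tree
}

#' Bend a section away from the somato-dendritic axis
#'
#' Rotates the section's distal point about its proximal point by `angle`
#' degrees away from the y axis (toward increasing |x|; purely vertical
#' sections rotate toward +x). The section length is unchanged and all
#' descendant sections are rigidly translated so connectivity is preserved.
#'
#' @param tree a [MorphologyTree-class].
#' @param section a section id.
#' @param angle degrees in [0, 90].
#' @return The modified tree.
#' @export
applyBend <- function(tree, section, angle) {
  s <- tree@sections
  i <- match(section, s$id)
  if (is.na(i)) stop("unknown section id: ", section)
  if (!is.finite(angle) || angle < 0 || angle > 90) {
    stop("angle must be in [0, 90] degrees")
  }
  v <- c(s$x1[i] - s$x0[i], s$y1[i] - s$y0[i])
  away <- if (v[1] > 0) 1 else if (v[1] < 0) -1 else 1
  ## rotating away from the y axis: for x >= 0 side rotate clockwise when
  ## pointing up (+y) and counter-clockwise when pointing down
  cw <- if (v[2] >= 0) -away else away
  v2 <- .rot2(v, cw * angle)
  new_distal <- c(s$x0[i], s$y0[i]) + v2
  shift <- new_distal - c(s$x1[i], s$y1[i])
  s$x1[i] <- new_distal[1]; s$y1[i] <- new_distal[2]
  ## translate descendants rigidly
  desc <- character(0); frontier <- s$id[i]
  repeat {
    kids <- s$id[!is.na(s$parent) & s$parent %in% frontier & !(s$id %in% desc)]
    if (!length(kids)) break
    desc <- c(desc, kids); frontier <- kids
  }
  j <- s$id %in% desc
  s$x0[j] <- s$x0[j] + shift[1]; s$y0[j] <- s$y0[j] + shift[2]
  s$x1[j] <- s$x1[j] + shift[1]; s$y1[j] <- s$y1[j] + shift[2]
  tree@sections <- s
  validObject(tree)
  tree
}

#' Path distance from the soma midpoint
#'
#' Distances are measured along the tree from the midpoint of the soma (the
#' recording point), so the soma's own half-length contributes to distances
#' of attached sections.
#'
#' @param tree a [MorphologyTree-class].
#' @param section a section id.
#' @param arc_position fraction along the section in [0, 1] (0 = proximal).
#' @return Distance in um.
#' @export
pathDistanceFromSoma <- function(tree, section, arc_position = 0.5) {
  s <- tree@sections
  i <- match(section, s$id)
  if (is.na(i)) stop("unknown section id: ", section)
  if (arc_position < 0 || arc_position > 1) stop("arc_position must be in [0, 1]")
  len <- sectionLengths(tree)
  root <- which(is.na(s$parent))
  if (i == root) return(unname(abs(arc_position - 0.5) * len[i]))
  d <- arc_position * len[i]
  j <- i
  repeat {
    p <- match(s$parent[j], s$id)
    if (p == root) {
      d <- d + switch(s$attach_end[j],
        proximal = len[root] / 2, distal = len[root] / 2, center = 0)
      break
    }
    d <- d + switch(s$attach_end[j],
      proximal = 0, distal = len[p], center = len[p] / 2)
    j <- p
  }
  unname(d)
}

#' @describeIn sectionLengths Number of sections.
#' @export
nSections <- function(tree) nrow(tree@sections)

#' Section geometry summaries
#'
#' @param tree a [MorphologyTree-class].
#' @return `sectionLengths`: named numeric of section lengths (um);
#'   `totalDendriticLength`: total cable length over dendritic sections (um);
#'   `nSections`: section count.
#' @export
sectionLengths <- function(tree) {
  s <- tree@sections
  setNames(sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2), s$id)
}

#' @describeIn sectionLengths Total dendritic cable length.
#' @export
totalDendriticLength <- function(tree) {
  s <- tree@sections
  sum(sectionLengths(tree)[s$kind %in% c("dend_proximal", "dend_distal")])
}

#' Access the section table of a morphology
#'
#' @param tree a [MorphologyTree-class].
#' @return The sections data.frame.
#' @export
sections <- function(tree) tree@sections

setMethod("show", "MorphologyTree", function(object) {
  s <- object@sections
  len <- sectionLengths(object)
  cat("MorphologyTree with", nrow(s), "sections\n")
  tab <- table(s$kind)
  cat("  kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  total cable: %.1f um (dendritic %.1f um)\n",
              sum(len), totalDendriticLength(object)))
  cat(sprintf("  y extent: [%.1f, %.1f] um\n",
              min(c(s$y0, s$y1)), max(c(s$y0, s$y1))))
})

setMethod("show", "ArtificialNeuronParams", function(object) {
  cat("ArtificialNeuronParams\n")
  for (nm in slotNames(object)) {
    v <- slot(object, nm)
    cat(sprintf("  %s: %s\n", nm, paste(format(v), collapse = ", ")))
  }
})
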