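## SWC morphology serialization. Standard 7-column dialect:
## index type x y z radius parent, '#' comments. Each parent link becomes one
## cylindrical section; type codes 1 = soma, 2 = axon, 3 (and anything else)
## = dendrite. z is read and stored in metadata but ignored by the planar
## geometry and the field coupling. The root soma sample is represented as a
## vertical cylinder of length 2*radius centered on the sample point (the
## spherical-soma convention); sections starting at the root sample attach at
## the soma midpoint.

#' Read a morphology from an SWC file
#'
#' @param path file path or connection.
#' @return A [MorphologyTree-class]. Section ids are `"swc<index>"` (the soma
#'   root is `"soma"`).
#' @export
readSWC <- function(path) {
  lines <- readLines(path, warn = FALSE)
  raw <- list()
  for (ln in seq_along(lines)) {
    txt <- sub("#.*$", "", lines[ln])
    txt <- trimws(txt)
    if (!nzchar(txt)) next
    f <- strsplit(txt, "[[:space:]]+")[[1]]
    if (length(f) != 7L) {
      stop(sprintf("SWC parse error at line %d: expected 7 columns, got %d", ln, length(f)))
    }
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v))) stop(sprintf("SWC parse error at line %d: non-numeric field", ln))
    raw[[length(raw) + 1L]] <- c(v, ln)
  }
  if (!length(raw)) stop("SWC parse error: no samples")
  m <- do.call(rbind, raw)
  colnames(m) <- c("index", "type", "x", "y", "z", "radius", "parent", "line")
  if (anyDuplicated(m[, "index"])) {
    dup <- m[duplicated(m[, "index"]), , drop = FALSE][1, ]
    stop(sprintf("SWC parse error at line %d: duplicate index %d",
                 dup["line"], dup["index"]))
  }
  roots <- which(m[, "parent"] == -1)
  if (length(roots) != 1L) stop("SWC parse error: expected exactly one root sample")
  bad <- which(m[, "parent"] != -1 & !(m[, "parent"] %in% m[, "index"]))
  if (length(bad)) {
    stop(sprintf("SWC parse error at line %d: parent index %d not defined",
                 m[bad[1], "line"], m[bad[1], "parent"]))
  }
  root <- m[roots, ]
  if (root["type"] != 1) stop("SWC parse error: root sample must be of soma type (1)")
  r <- root["radius"]
  if (r <= 0) stop("SWC parse error: root radius must be positive")
  rows <- list(.sectionRow("soma", "soma",
                           c(root["x"], root["y"] - r), c(root["x"], root["y"] + r),
                           2 * r))
  sec_of_sample <- setNames("soma", as.character(root["index"]))
  ## topological order: repeatedly emit samples whose parent is placed
  placed <- as.character(root["index"])
  todo <- setdiff(as.character(m[, "index"]), placed)
  ord <- character(0)
  while (length(todo)) {
    par_ok <- as.character(m[match(as.numeric(todo), m[, "index"]), "parent"]) %in% placed
    if (!any(par_ok)) stop("SWC parse error: cyclic parent links")
    nxt <- todo[par_ok]
    ord <- c(ord, nxt)
    placed <- c(placed, nxt)
    todo <- setdiff(todo, nxt)
  }
  soma_center <- c(root["x"], root["y"])
  for (key in ord) {
    i <- match(as.numeric(key), m[, "index"])
    pi <- match(m[i, "parent"], m[, "index"])
    p_xy <- c(m[pi, "x"], m[pi, "y"])
    xy <- c(m[i, "x"], m[i, "y"])
    if (sqrt(sum((xy - p_xy)^2)) <= 0) {
      stop(sprintf("SWC parse error at line %d: zero-length segment", m[i, "line"]))
    }
    type <- m[i, "type"]
    parent_sec <- sec_of_sample[[as.character(m[i, "parent"])]]
    attach <- if (m[i, "parent"] == root["index"]) "center" else "distal"
    kind <- if (type == 2) "axon" else if (type == 1) {
      ## non-root soma samples: perisomatic cable; classify by geometry
      ## (above the soma midpoint: dendritic trunk, below: axon hillock)
      if (xy[2] >= soma_center[2]) "dend_proximal" else "axon"
    } else {
      if (parent_sec == "soma") "dend_proximal" else "dend_distal"
    }
    id <- paste0("swc", as.integer(m[i, "index"]))
    rows[[length(rows) + 1L]] <- .sectionRow(id, kind, p_xy, xy,
                                             2 * m[i, "radius"],
                                             parent = parent_sec,
                                             attach_end = attach)
    sec_of_sample[[key]] <- id
  }
  s <- do.call(rbind, rows)
  tree <- new("MorphologyTree", sections = s,
              metadata = list(source = "swc",
                              z = setNames(m[, "z"], paste0("swc", as.integer(m[, "index"])))))
  validObject(tree)
  tree
}

#' Write a morphology to an SWC file
#'
#' The soma is emitted as a single spherical sample at its midpoint with
#' radius `diam/2` (faithful round-trip when soma length equals its
#' diameter, as for SWC-derived trees); every other section contributes one
#' sample at its distal point.
#'
#' @param tree a [MorphologyTree-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeSWC <- function(tree, path) {
  validObject(tree)
  s <- tree@sections
  root <- which(is.na(s$parent))
  idx <- integer(nrow(s))
  idx[root] <- 1L
  order_ids <- .topoOrder(s)
  k <- 1L
  out <- character(0)
  cx <- (s$x0[root] + s$x1[root]) / 2
  cy <- (s$y0[root] + s$y1[root]) / 2
  out[1] <- sprintf("1 1 %.6f %.6f 0.000000 %.6f -1", cx, cy, s$diam[root] / 2)
  type_of <- c(soma = 1L, axon = 2L, axon_terminal = 2L,
               dend_proximal = 3L, dend_distal = 3L)
  for (id in order_ids) {
    i <- match(id, s$id)
    if (i == root) next
    k <- k + 1L
    idx[i] <- k
    p <- match(s$parent[i], s$id)
    out[k] <- sprintf("%d %d %.6f %.6f 0.000000 %.6f %d",
                      k, type_of[[s$kind[i]]], s$x1[i], s$y1[i],
                      s$diam[i] / 2, idx[p])
  }
  writeLines(c("# generated by cableEF", out), path)
  invisible(path)
}

## parent-before-child ordering of section ids
.topoOrder <- function(s) {
  root <- s$id[is.na(s$parent)]
  ord <- root
  repeat {
    kids <- s$id[!is.na(s$parent) & s$parent %in% ord & !(s$id %in% ord)]
    if (!length(kids)) break
    ord <- c(ord, kids)
  }
  ord
}
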