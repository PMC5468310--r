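test_that("default artificial neuron has the reference layout", {
  tree <- fix_tree
  expect_equal(nSections(tree), 14L)
  s <- sections(tree)
  expect_equal(sum(s$kind == "soma"), 1L)
  expect_equal(sum(s$kind == "axon"), 1L)
  expect_equal(sum(s$kind == "dend_proximal"), 4L)
  expect_equal(sum(s$kind == "dend_distal"), 8L)
  ## soma centered at the origin, axon toward -y, dendrites toward +y
  soma <- s[s$kind == "soma", ]
  expect_equal((soma$y0 + soma$y1) / 2, 0)
  expect_lt(s$y1[s$id == "axon"], 0)
  expect_true(all(s$y1[grepl("^dend", s$id)] > 0))
  ## distal dendrites attach to proximal ones, proximal to the soma
  expect_true(all(s$parent[s$kind == "dend_distal"] %in%
                    s$id[s$kind == "dend_proximal"]))
  expect_true(all(s$parent[s$kind == "dend_proximal"] == "soma"))
})

test_that("building is a pure function of the parameters", {
  expect_identical(buildArtificialNeuron(), buildArtificialNeuron())
  p <- artificialNeuronParams(dend_bend_angle = 0)
  expect_identical(buildArtificialNeuron(p), buildArtificialNeuron(p))
})

test_that("removing all dendrites leaves soma and axon", {
  p <- artificialNeuronParams(removed_dendrites = paste0("dend", 1:12))
  tree <- buildArtificialNeuron(p)
  expect_equal(sort(sections(tree)$id), c("axon", "soma"))
  ## removing a proximal dendrite removes its distal children too
  p2 <- artificialNeuronParams(removed_dendrites = "dend4")
  tree2 <- buildArtificialNeuron(p2)
  expect_false(any(c("dend4", "dend8", "dend12") %in% sections(tree2)$id))
})

test_that("removal reduces dendritic cable by exactly the removed lengths", {
  full <- totalDendriticLength(fix_tree)
  len <- sectionLengths(fix_tree)
  gone <- c("dend11", "dend12")
  pruned <- buildArtificialNeuron(
    artificialNeuronParams(removed_dendrites = gone))
  expect_equal(totalDendriticLength(pruned), full - sum(len[gone]))
})

test_that("invalid parameters are rejected with the field named", {
  expect_error(artificialNeuronParams(soma_diameter = -1), "soma_diameter")
  expect_error(artificialNeuronParams(dend_bend_angle = 120), "dend_bend_angle")
  expect_error(artificialNeuronParams(axon_length = 0), "axon_length")
  expect_error(updateParams(artificialNeuronParams(), nonsense = 1), "nonsense")
})

test_that("applyBend rotates rigidly and preserves lengths", {
  tree <- fix_tree
  expect_equal(applyBend(tree, "dend1", 0), tree)
  bent <- applyBend(tree, "axon", 90)
  s <- sections(bent)
  ax <- s[s$id == "axon", ]
  expect_equal(ax$y0, ax$y1, tolerance = 1e-12)
  for (ang in c(15, 45, 77)) {
    b <- applyBend(tree, "dend2", ang)
    expect_equal(unname(sectionLengths(b)), unname(sectionLengths(tree)),
                 tolerance = 1e-9)
    expect_true(validObject(b)) # descendants still attached
    expect_equal(sections(b)$diam, sections(tree)$diam)
  }
  expect_error(applyBend(tree, "nope", 10), "unknown section")
  expect_error(applyBend(tree, "axon", 91), "angle")
})

test_that("bending a proximal dendrite translates its distal children", {
  bent <- applyBend(fix_tree, "dend1", 30)
  s0 <- sections(fix_tree); s1 <- sections(bent)
  kids <- s0$id[s0$parent == "dend1" & !is.na(s0$parent)]
  expect_length(kids, 2L)
  for (k in kids) {
    i0 <- match(k, s0$id); i1 <- match(k, s1$id)
    v0 <- c(s0$x1[i0] - s0$x0[i0], s0$y1[i0] - s0$y0[i0])
    v1 <- c(s1$x1[i1] - s1$x0[i1], s1$y1[i1] - s1$y0[i1])
    expect_equal(v1, v0, tolerance = 1e-12) # translated, not rotated
  }
})

test_that("path distance follows the soma-midpoint convention", {
  expect_equal(pathDistanceFromSoma(fix_tree, "soma", 0.5), 0)
  expect_equal(pathDistanceFromSoma(fix_tree, "axon", 1), 55)
  expect_equal(pathDistanceFromSoma(fix_tree, "dend8", 1), 15) # 5 + 8 + 2
  expect_equal(pathDistanceFromSoma(fix_tree, "dend1", 0), 5)
  expect_error(pathDistanceFromSoma(fix_tree, "ghost"), "unknown section")
})

test_that("dendrite counts generalize with the round-robin layout", {
  for (nd in c(0L, 1L, 3L, 6L, 9L)) {
    tree <- buildArtificialNeuron(artificialNeuronParams(n_dendrites = nd))
    s <- sections(tree)
    expect_equal(sum(grepl("^dend", s$id)), nd)
    expect_true(validObject(tree))
  }
  tree12 <- buildArtificialNeuron(artificialNeuronParams(n_dendrites = 12L))
  expect_identical(sections(tree12), sections(fix_tree))
})

test_that("axon terminal branches appear only for n_axon_terminals >= 2", {
  t1 <- buildArtificialNeuron(artificialNeuronParams(n_axon_terminals = 1L))
  expect_equal(sum(sections(t1)$kind == "axon_terminal"), 0L)
  t3 <- buildArtificialNeuron(
    artificialNeuronParams(n_axon_terminals = 3L,
                           axon_terminal_branch_angle = 40))
  s <- sections(t3)
  expect_equal(sum(s$kind == "axon_terminal"), 3L)
  expect_true(all(s$parent[s$kind == "axon_terminal"] == "axon"))
  expect_equal(unname(sectionLengths(t3)[s$kind == "axon_terminal"]),
               rep(20, 3), tolerance = 1e-9)
})
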