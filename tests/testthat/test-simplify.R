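# a linear chain graph with given labels
chain_graph <- function(labels) {
  n <- length(labels)
  e <- if (n > 1L) cbind(node_encode(1:(n - 1L)), node_encode(2:n)) else NULL
  bd_graph(labels, e)
}

test_that("pruning leaves linear chains untouched for any parameters", {
  g <- chain_graph(c("AC", "G", "TTT", "A", "CCGG"))
  for (mc in c(0L, 1L, 3L)) {
    gp <- prune(g, prune_params(k = 24L, max_choices = mc,
                                min_component_bp = 1L))
    expect_identical(gp$labels, g$labels)
    expect_identical(gp$edges, g$edges)
  }
})

bubble_cluster <- function(flank_len) {
  # flank, then 5 adjacent biallelic 1 bp bubbles, then flank
  labels <- c(`1` = paste(rep("A", flank_len), collapse = ""))
  edges <- NULL
  id <- 1L
  prev <- 1L
  for (b in 1:5) {
    x <- id + 1L
    y <- id + 2L
    z <- id + 3L
    labels[as.character(c(x, y, z))] <- c("C", "G", "T")
    edges <- rbind(edges,
                   c(node_encode(prev), node_encode(x)),
                   c(node_encode(prev), node_encode(y)),
                   c(node_encode(x), node_encode(z)),
                   c(node_encode(y), node_encode(z)))
    prev <- z
    id <- z
  }
  tail_id <- id + 1L
  labels[as.character(tail_id)] <- paste(rep("A", flank_len), collapse = "")
  edges <- rbind(edges, c(node_encode(prev), node_encode(tail_id)))
  bd_graph(labels, edges)
}

test_that("a dense cluster of bubbles within the window is pruned away", {
  # short flanks: every 24 bp window through the cluster crosses most of
  # its ten choice edges, so everything but the forced tail edge goes
  g <- bubble_cluster(1L)
  gp <- prune(g, prune_params(k = 24L, max_choices = 3L,
                              min_component_bp = 1L))
  forced <- c(node_encode(16L), node_encode(17L))  # z5 -> tail, sole/sole
  expect_identical(nrow(gp$edges), 2L)  # the forced edge and its mirror
  expect_true(paste(forced[1], forced[2]) %in%
                paste(gp$edges[, 1], gp$edges[, 2]))
  # permissive threshold: nothing is removed
  gp2 <- prune(g, prune_params(k = 24L, max_choices = 10L,
                               min_component_bp = 1L))
  expect_identical(nrow(gp2$edges), nrow(g$edges))
  # long flanks: windows lying mostly in a flank rescue the boundary edges
  gl <- bubble_cluster(30L)
  gpl <- prune(gl, prune_params(k = 24L, max_choices = 3L,
                                min_component_bp = 1L))
  expect_true(paste(node_encode(1L), node_encode(2L)) %in%
                paste(gpl$edges[, 1], gpl$edges[, 2]))
  expect_lt(nrow(gpl$edges), nrow(gl$edges))
})

test_that("small disconnected components are deleted, reference restored", {
  labels <- c(`1` = paste(rep("A", 40), collapse = ""),
              `2` = paste(rep("C", 40), collapse = ""),
              `3` = "ACGTACGTAC")  # isolated 10 bp component
  g <- bd_graph(labels, rbind(c(node_encode(1L), node_encode(2L))))
  gp <- prune(g, prune_params(min_component_bp = 33L))
  expect_identical(sort(names(gp$labels)), c("1", "2"))
  g$reference_paths <- list(ref = node_encode(3L))
  gp2 <- prune(g, prune_params(min_component_bp = 33L,
                               restore_reference = TRUE))
  expect_true("3" %in% names(gp2$labels))
})

test_that("complement components find removed regions and their borders", {
  idx <- gbwt_build(f1$paths)
  gi <- induced_graph(f1$graph, idx)
  # nothing pruned: no components
  expect_identical(complement_components(gi, f1$graph), list())
  # delete nodes 2 and 3: one component with border {1, 4}
  keep <- c(1L, 4L, 5L)
  e <- f1$graph$edges
  sel <- (e[, 1] %/% 2) %in% keep & (e[, 2] %/% 2) %in% keep
  gp <- bd_graph(f1$graph$labels[as.character(keep)], e[sel, , drop = FALSE])
  comps <- complement_components(gi, gp)
  expect_identical(length(comps), 1L)
  expect_identical(comps[[1]]$border, c(1L, 4L))
  expect_identical(comps[[1]]$internal, c(2L, 3L))
  # everything pruned away: a single region
  comps2 <- complement_components(gi, bd_graph(f1$graph$labels,
                                               matrix(integer(0), ncol = 2)))
  expect_identical(length(comps2), 1L)
  # two pruned bubbles separated by an intact edge: two components
  labels <- c(`1` = "A", `2` = "C", `3` = "G", `4` = "T", `5` = "A",
              `6` = "C", `7` = "G", `8` = "T")
  ed <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(3L, 4L), c(4L, 5L),
              c(5L, 6L), c(5L, 7L), c(6L, 8L), c(7L, 8L))
  g2 <- bd_graph(labels, cbind(node_encode(ed[, 1]), node_encode(ed[, 2])))
  paths <- list(node_encode(c(1L, 2L, 4L, 5L, 6L, 8L)),
                node_encode(c(1L, 3L, 4L, 5L, 7L, 8L)))
  idx2 <- gbwt_build(paths)
  gp3 <- bd_graph(labels[c("1", "4", "5", "8")],
                  rbind(c(node_encode(4L), node_encode(5L))))
  comps3 <- complement_components(induced_graph(g2, idx2), gp3)
  expect_identical(length(comps3), 2L)
  expect_identical(comps3[[1]]$border, c(1L, 4L))
  expect_identical(comps3[[2]]$border, c(5L, 8L))
})

test_that("maximal path search respects haplotype support", {
  idx <- gbwt_build(f1$paths)
  gi <- induced_graph(f1$graph, idx)
  keep <- c(1L, 4L, 5L)
  e <- f1$graph$edges
  sel <- (e[, 1] %/% 2) %in% keep & (e[, 2] %/% 2) %in% keep
  gp <- bd_graph(f1$graph$labels[as.character(keep)], e[sel, , drop = FALSE])
  comp <- complement_components(gi, gp)[[1]]
  mp <- find_maximal_paths(comp, idx)
  keys <- sort(vapply(mp, paste, character(1), collapse = " "))
  # exactly the two supported border-to-border routes 1-2-4 and 1-3-4;
  # no alternative mixing P0's and P1's alleles exists
  expect_identical(keys, c("2 4 8", "2 6 8"))
  # a component no haplotype touches yields nothing
  lonely <- list(ids = c(9L, 10L), border = integer(0),
                 internal = c(9L, 10L),
                 edges = rbind(c(node_encode(9L), node_encode(10L))))
  expect_identical(find_maximal_paths(lonely, idx), list())
  expect_identical(find_maximal_paths(comp, gbwt_build(list())), list())
})

test_that("a haplotype crossing a region twice yields two maximal paths", {
  # A -(x|y)- M -(x2|y2)- B with both bubbles pruned; border {A, M, B}
  labels <- c(A = "AAAA", x = "C", y = "G", M = "TTTT", x2 = "C", y2 = "G",
              B = "AAAA")
  names(labels) <- as.character(1:7)
  ed <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(3L, 4L),
              c(4L, 5L), c(4L, 6L), c(5L, 7L), c(6L, 7L))
  g <- bd_graph(labels, cbind(node_encode(ed[, 1]), node_encode(ed[, 2])))
  paths <- list(node_encode(c(1L, 2L, 4L, 5L, 7L)),
                node_encode(c(1L, 3L, 4L, 6L, 7L)))
  idx <- gbwt_build(paths)
  gp <- bd_graph(labels[c("1", "4", "7")], NULL)
  comps <- complement_components(induced_graph(g, idx), gp)
  expect_identical(length(comps), 1L)
  mp <- find_maximal_paths(comps[[1]], idx)
  expect_identical(length(mp), 4L)  # two per bubble, no recombinants
  sim <- simplify(g, idx, pruned = gp)
  for (p in paths) expect_true(path_embeddable(sim$graph, sim$mapping, p))
})

test_that("unfolding does not create recombinants inside a component", {
  # a bubble with two-node alleles: A -(x1 x2 | y1 y2)- B, both alleles
  # supported, pruned away entirely; switching alleles mid-bubble must not
  # be representable in the unfolded graph
  labels <- c(`1` = "AAAA", `2` = "C", `3` = "A", `4` = "G", `5` = "T",
              `6` = "TTTT")
  ed <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 6L),
              c(1L, 4L), c(4L, 5L), c(5L, 6L))
  g <- bd_graph(labels, cbind(node_encode(ed[, 1]), node_encode(ed[, 2])))
  paths <- list(node_encode(c(1L, 2L, 3L, 6L)),
                node_encode(c(1L, 4L, 5L, 6L)))
  idx <- gbwt_build(paths)
  gp <- bd_graph(labels[c("1", "6")], NULL)
  sim <- simplify(g, idx, pruned = gp)
  for (p in paths) expect_true(path_embeddable(sim$graph, sim$mapping, p))
  expect_false(path_embeddable(sim$graph, sim$mapping,
                               node_encode(c(1L, 2L, 5L, 6L))))
  expect_false(path_embeddable(sim$graph, sim$mapping,
                               node_encode(c(1L, 4L, 3L, 6L))))
  # tightness: translated border-to-border routes equal the maximal set
  ci <- sim$components[[1]]
  mx <- sort(vapply(ci$maximal_paths, paste, character(1), collapse = ","))
  adj <- split(ci$added_edges[, 2], ci$added_edges[, 1])
  res <- list()
  dfs <- function(v, path) {
    tid <- translate(sim$mapping, v) %/% 2L
    if (length(path) >= 2L && tid %in% ci$border) {
      res[[length(res) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (w in adj[[as.character(v)]]) dfs(w, c(path, w))
  }
  for (b in ci$border) {
    for (v in c(node_encode(b), node_encode(b, TRUE))) {
      if (!is.null(adj[[as.character(v)]])) dfs(v, v)
    }
  }
  tr <- unique(vapply(res, function(p) {
    paste(graphbwt:::canonical_path(translate(sim$mapping, p)), collapse = ",")
  }, character(1)))
  expect_identical(sort(tr), mx)
})

test_that("unfolding a single maximal path reuses borders and duplicates interior", {
  labels <- c(`1` = "A", `2` = "C", `3` = "G", `4` = "T")
  comp <- list(ids = 1:4, border = c(1L, 4L), internal = c(2L, 3L),
               edges = close_symmetry(rbind(
                 c(node_encode(1L), node_encode(2L)),
                 c(node_encode(2L), node_encode(3L)),
                 c(node_encode(3L), node_encode(4L)))))
  g <- bd_graph(labels, comp$edges)
  mp <- list(node_encode(1:4))
  uf <- unfold_component(g, comp, mp, labels, next_id = 5L)
  expect_identical(nrow(uf$nodes), 2L)         # two duplicates
  expect_identical(uf$nodes$orig, c(2L, 3L))   # of nodes 2 and 3
  expect_identical(nrow(uf$edges), 3L)         # chain of 4 nodes
  # two paths sharing their first two nodes share the prefix duplicate
  mp2 <- list(node_encode(c(1L, 2L, 3L)), node_encode(c(1L, 2L, 4L)))
  comp2 <- list(ids = 1:4, border = c(1L, 3L, 4L), internal = 2L,
                edges = close_symmetry(rbind(
                  c(node_encode(1L), node_encode(2L)),
                  c(node_encode(2L), node_encode(3L)),
                  c(node_encode(2L), node_encode(4L)))))
  uf2 <- unfold_component(g, comp2, mp2, labels, next_id = 5L)
  expect_identical(nrow(uf2$nodes), 1L)        # node 2 duplicated once
})

test_that("translate is an orientation-respecting substitution", {
  idx <- gbwt_build(f1$paths)
  keep <- c(1L, 4L, 5L)
  e <- f1$graph$edges
  sel <- (e[, 1] %/% 2) %in% keep & (e[, 2] %/% 2) %in% keep
  gp <- bd_graph(f1$graph$labels[as.character(keep)], e[sel, , drop = FALSE])
  sim <- simplify(f1$graph, idx, pruned = gp)
  # identity on originals
  expect_identical(translate(sim$mapping, node_encode(c(1L, 5L))),
                   node_encode(c(1L, 5L)))
  # duplicates map back to original ids
  dups <- as.integer(names(sim$mapping$map))
  expect_true(length(dups) >= 2L)
  for (d in dups) {
    tr <- translate(sim$mapping, node_encode(d))
    expect_true((tr %/% 2L) %in% c(2L, 3L))
    # reversal commutes with translation
    p <- c(node_encode(1L), node_encode(d))
    expect_identical(translate(sim$mapping, reverse_path(p)),
                     reverse_path(translate(sim$mapping, p)))
  }
  expect_error(translate(sim$mapping, node_encode(999L)), "neither")
})

test_that("simplify with nothing pruned returns the graph with empty mapping", {
  idx <- gbwt_build(f1$paths)
  sim <- simplify(f1$graph, idx, pruned = f1$graph)
  expect_identical(sim$graph$labels, f1$graph$labels)
  expect_identical(sim$graph$edges, f1$graph$edges)
  expect_identical(length(sim$mapping$map), 0L)
  expect_identical(sim$components, list())
})

test_that("simplification retains all haplotype paths on random prunings", {
  for (seed in c(3, 8, 17)) {
    fx <- gen_fixture(rand_spec(seed, max_ids = 25L, max_paths = 10L))
    idx <- gbwt_build(fx$paths)
    gp <- random_pruned(fx$graph, seed)
    sim <- simplify(fx$graph, idx, pruned = gp)
    for (p in fx$paths) {
      expect_true(path_embeddable(sim$graph, sim$mapping, p))
    }
    # haplotype k-mers are all spelled by the simplified graph
    hk <- unique(unlist(lapply(fx$paths, function(p)
      sequence_kmers(path_sequence(fx$graph, p), 6L))))
    expect_true(all(hk %in% spelled_kmers(sim$graph, 6L)))
  }
})
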