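# shared fixture helpers for the suite

f1 <- fixture_f1()

# a varied random spec: sizes bounded, cyclic and sparse-id cases included
rand_spec <- function(seed, max_ids = 40L, max_paths = 30L, max_len = 60L) {
  set.seed(seed * 7L + 1L)
  fixture_spec(seed,
               n_ids = sample(5:max_ids, 1),
               bubble_density = runif(1, 0.2, 0.9),
               n_paths = sample(1:max_paths, 1),
               max_len = sample(3:max_len, 1),
               recomb = sample(c(0, runif(2, 0.05, 0.4)), 1),
               cycles = seed %% 3L == 0L,
               id_offset = if (seed %% 7L == 0L) 50L else 0L)
}

# the exact sequences an index holds for a path list
indexed_sequences <- function(paths, both) {
  if (!both) return(paths)
  unlist(lapply(paths, function(p) list(p, reverse_path(p))),
         recursive = FALSE)
}

expect_gbwt_identical <- function(a, b) {
  expect_true(gbwt_identical(a, b))
}

# record-by-record (and document-array) equality against the oracle
expect_matches_oracle <- function(index, oracle) {
  expect_setequal(index$core$nodes, as.integer(names(oracle$records)))
  for (v in names(oracle$records)) {
    r <- gbwt_record(index, as.integer(v))
    o <- oracle$records[[v]]
    expect_identical(r$header$successor, o$header$successor)
    expect_identical(r$header$rank, o$header$rank)
    expect_identical(r$runs$successor, o$runs$successor)
    expect_identical(r$runs$length, o$runs$length)
    if (v != "0") {
      st <- list(node = as.integer(v), sp = 0L, ep = r$body_length - 1L)
      expect_identical(gbwt_locate(index, st), o$ids)
    }
  }
}

# random pruned subgraph: drop a fraction of symmetric edge pairs, and
# optionally delete some internal node ids outright
random_pruned <- function(graph, seed, edge_frac = 0.3, node_frac = 0.15) {
  set.seed(seed * 13L + 5L)
  e <- graph$edges
  canon <- paste(pmin(e[, 1L], bitwXor(e[, 2L], 1L)),
                 pmax(e[, 2L], bitwXor(e[, 1L], 1L)))
  u <- unique(canon)
  dropu <- sample(u, ceiling(length(u) * edge_frac))
  e <- e[!(canon %in% dropu), , drop = FALSE]
  ids <- as.integer(names(graph$labels))
  del <- sample(ids, floor(length(ids) * node_frac))
  keep <- setdiff(ids, del)
  e <- e[(e[, 1L] %/% 2L) %in% keep & (e[, 2L] %/% 2L) %in% keep, ,
         drop = FALSE]
  bd_graph(graph$labels[as.character(sort(keep))], e,
           reference_paths = graph$reference_paths)
}
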