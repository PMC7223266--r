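test_that("index records and document arrays equal the oracle on varied fixtures", {
  for (seed in 1:12) {
    sp <- rand_spec(seed, max_ids = 30L, max_paths = 12L)
    fx <- gen_fixture(sp)
    both <- seed %% 2L == 0L
    d <- if (seed %% 4L == 0L) 3L else 1024L
    idx <- gbwt_build(fx$paths, both_orientations = both, sample_interval = d)
    or <- naive_gbwt(indexed_sequences(fx$paths, both))
    expect_matches_oracle(idx, or)
    # conservation: body occurrences of w = visits to w; $ occurrences = paths
    seqs <- indexed_sequences(fx$paths, both)
    visits <- table(unlist(seqs))
    co <- idx$core
    occ <- tapply(co$run_len, co$run_succ, sum)
    expect_identical(as.integer(occ[["0"]]), length(seqs))
    for (v in names(visits)) {
      expect_identical(as.integer(occ[[v]]), as.integer(visits[[v]]))
    }
  }
})

test_that("positional LF-mapping matches the hand-derived F1 examples", {
  idx <- gbwt_build(f1$paths, both_orientations = FALSE)
  expect_identical(gbwt_lf(idx, 2L, 0L, 4L), list(node = 4L, offset = 0L))
  # third visit to node 1 is path P2; its visit to node 2 sorts at offset 1
  expect_identical(gbwt_lf(idx, 2L, 2L, 4L), list(node = 4L, offset = 1L))
  # successor with no prior occurrences at offset 0
  expect_identical(gbwt_lf(idx, 8L, 0L, 10L), list(node = 10L, offset = 0L))
  # absent successor: search-failure signal, not an exception
  expect_null(gbwt_lf(idx, 2L, 0L, 10L))
  expect_error(gbwt_lf(idx, 2L, 0L, 0L), "end-marker")
})

test_that("LF-mapping is a bijection onto non-end-marker record positions", {
  for (seed in c(2, 3, 9)) {
    fx <- gen_fixture(rand_spec(seed, max_ids = 20L, max_paths = 8L))
    idx <- gbwt_build(fx$paths, both_orientations = seed %% 2L == 0L)
    co <- idx$core
    images <- character(0)
    all_pos <- character(0)
    for (ri in seq_along(co$nodes)) {
      v <- co$nodes[ri]
      for (i in seq_len(co$blen[ri]) - 1L) {
        if (v != 0L) all_pos <- c(all_pos, paste(v, i))
        w <- graphbwt:::gbwt_body_at_cpp(co, v, i)
        if (w > 0L) {
          p <- gbwt_lf(idx, v, i, w)
          images <- c(images, paste(p$node, p$offset))
        }
      }
    }
    expect_identical(sort(images), sort(all_pos))
  }
})

test_that("record_rank counts successors by scanning runs", {
  idx <- gbwt_build(f1$paths, both_orientations = FALSE)
  rec <- gbwt_record(idx, 2L)   # body successors 4, 6, 4
  expect_identical(record_rank(rec, 3L, 4L), 2L)
  expect_identical(record_rank(rec, 1L, 4L), 1L)
  expect_identical(record_rank(rec, 0L, 4L), 0L)
  expect_identical(record_rank(rec, 2L, 99L), 0L)  # absent successor
  rec4 <- gbwt_record(idx, 8L)  # single run (10, 3)
  expect_identical(record_rank(rec4, 2L, 10L), 2L)
  expect_error(record_rank(rec4, 4L, 10L), "body length")
})

test_that("extend narrows ranges and propagates emptiness", {
  idx <- gbwt_build(f1$paths, both_orientations = FALSE)
  s <- gbwt_find(idx, 4L)                      # node 2 forward, both visits
  expect_identical(state_size(s), 2L)
  s2 <- gbwt_extend(idx, s, 8L)
  expect_identical(list(s2$node, s2$sp, s2$ep), list(8L, 0L, 1L))
  expect_identical(state_size(gbwt_extend(idx, s, 10L)), 0L)
  expect_identical(state_size(gbwt_extend(idx, gbwt_extend(idx, s, 10L), 8L)), 0L)
})

test_that("find counts subpath occurrences; orientations only when indexed", {
  idx <- gbwt_build(f1$paths, both_orientations = FALSE)
  expect_identical(state_size(gbwt_find(idx, node_encode(c(1L, 2L)))), 2L)
  expect_identical(state_size(gbwt_find(idx, node_encode(c(2L, 4L)))), 2L)
  expect_identical(state_size(gbwt_find(idx, node_encode(c(4L, 5L)))), 3L)
  expect_identical(state_size(gbwt_find(idx, node_encode(1L, TRUE))), 0L)
  expect_error(gbwt_find(idx, integer(0)), "empty pattern")
  both <- gbwt_build(f1$paths, both_orientations = TRUE)
  expect_identical(state_size(gbwt_find(both, node_encode(1L, TRUE))), 3L)
})

test_that("locate returns the oracle multiset, direct in range order", {
  idx <- gbwt_build(f1$paths, both_orientations = FALSE)
  s <- gbwt_find(idx, node_encode(c(2L, 4L)))
  expect_identical(sort(gbwt_locate(idx, s)), c(0L, 2L))
  expect_identical(gbwt_locate(idx, s, "fast"), c(0L, 2L))
  s <- gbwt_find(idx, node_encode(c(4L, 5L)))
  expect_identical(sort(gbwt_locate(idx, s)), 0:2)
  expect_identical(gbwt_locate(idx, graphbwt:::empty_state()), integer(0))
  # locate_fast == locate_direct on every occurring subpath of length <= 4
  for (seed in c(4, 10)) {
    fx <- gen_fixture(rand_spec(seed, max_ids = 20L, max_paths = 10L))
    idx <- gbwt_build(fx$paths, sample_interval = if (seed == 4) 2L else 1024L)
    seqs <- indexed_sequences(fx$paths, TRUE)
    tab <- naive_subpath_table(seqs, 4L)
    for (e in tab) {
      s <- gbwt_find(idx, e$pattern)
      expect_identical(state_size(s), e$count)
      expect_identical(sort(gbwt_locate(idx, s)), e$ids)
      expect_identical(gbwt_locate(idx, s, "fast"), e$ids)
    }
  }
})

test_that("extract round-trips every inserted sequence", {
  p <- node_encode(c(3L, 3L, 7L))
  idx1 <- gbwt_build(list(p), both_orientations = FALSE)
  expect_identical(gbwt_extract(idx1, 0L), p)
  idx <- gbwt_build(f1$paths, both_orientations = FALSE)
  expect_identical(gbwt_extract(idx, 1L), node_encode(c(1L, 3L, 4L, 5L)))
  expect_error(gbwt_extract(idx, 3L), "out of range")
  expect_error(gbwt_extract(idx, -1L), "out of range")
  for (seed in c(5, 6)) {
    fx <- gen_fixture(rand_spec(seed))
    both <- seed %% 2L == 0L
    idx <- gbwt_build(fx$paths, both_orientations = both)
    seqs <- indexed_sequences(fx$paths, both)
    for (j in seq_along(seqs)) {
      expect_identical(gbwt_extract(idx, j - 1L), as.integer(seqs[[j]]))
    }
  }
})

test_that("run counts for repeated identical paths do not grow with copies", {
  p <- node_encode(c(1L, 2L, 4L, 5L))
  runs_for <- function(m) {
    idx <- gbwt_build(rep(list(p), m), both_orientations = FALSE)
    hdr <- lengths(split(idx$core$hdr_succ, rep(seq_along(idx$core$nodes),
                                                diff(idx$core$hdr_ptr))))
    rn <- diff(idx$core$run_ptr)
    expect_true(all(rn <= hdr))
    rn
  }
  expect_identical(runs_for(10L), runs_for(100L))
})

test_that("empty and single-path indexes behave", {
  e <- gbwt_build(list())
  expect_identical(gbwt_n_sequences(e), 0L)
  expect_identical(state_size(gbwt_find(e, 2L)), 0L)
  expect_identical(gbwt_locate(e, gbwt_find(e, 2L)), integer(0))
  s <- gbwt_stats(e)
  expect_identical(s$runs, 0L)
  one <- gbwt_build(list(6L), both_orientations = FALSE)
  expect_identical(gbwt_record(one, 6L)$runs$successor, 0L)
  expect_identical(gbwt_extract(one, 0L), 6L)
})
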