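# Synthetic graph/haplotype generation plus a brute-force reverse-prefix
# sorting oracle. The oracle defines ground truth for every GBWT structure
# and query: it enumerates all occurrences (including the per-path
# end-marker occurrences), sorts them by reversed-prefix key with distinct
# end-markers breaking ties by path id, and partitions them into per-node
# record views.

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification for a synthetic fixture
#'
#' @param seed Integer seed; the same spec always generates the same fixture.
#' @param n_ids Upper bound on the number of graph ids.
#' @param bubble_density Probability that a backbone segment is a biallelic
#'   bubble rather than a single node.
#' @param n_paths Number of generated haplotype paths.
#' @param max_len Maximum path length in nodes.
#' @param recomb Per-junction probability of switching founder haplotypes.
#'   With `recomb = 0` every generated path is an exact founder copy.
#' @param cycles Add a back edge, making the graph cyclic.
#' @param id_offset Shift all graph ids upward (sparse-id fixtures).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed, n_ids = 20L, bubble_density = 0.5,
                         n_paths = 10L, max_len = 60L, recomb = 0.1,
                         cycles = FALSE, id_offset = 0L) {
  structure(list(seed = as.integer(seed), n_ids = as.integer(n_ids),
                 bubble_density = bubble_density,
                 n_paths = as.integer(n_paths), max_len = as.integer(max_len),
                 recomb = recomb, cycles = isTRUE(cycles),
                 id_offset = as.integer(id_offset)),
            class = "fixture_spec")
}

#' The fixed exemplar fixture F1
#'
#' A five-node bubble graph (labels G, A, T, GGG, C; edges 1-2, 1-3, 2-4,
#' 3-4, 4-5) with three forward paths: 1 2 4 5, 1 3 4 5 and 1 2 4 5 again.
#'
#' @return A list with `graph` (a `bdgraph`) and `paths`.
#' @export
fixture_f1 <- function() {
  labels <- c(`1` = "G", `2` = "A", `3` = "T", `4` = "GGG", `5` = "C")
  e <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(3L, 4L), c(4L, 5L))
  edges <- cbind(node_encode(e[, 1L]), node_encode(e[, 2L]))
  graph <- bd_graph(labels, edges)
  paths <- list(node_encode(c(1L, 2L, 4L, 5L)),
                node_encode(c(1L, 3L, 4L, 5L)),
                node_encode(c(1L, 2L, 4L, 5L)))
  list(graph = graph, paths = paths)
}

#' Generate a synthetic fixture
#'
#' Builds a bubble-chain variation graph (optionally cyclic) and generates
#' haplotype paths as founder-following walks with recombination switches,
#' occasional duplicates, sub-walks and single-node paths.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `graph` (a `bdgraph`) and `paths` (list of oriented
#'   node vectors, all valid paths of the graph).
#' @export
gen_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, {
    off <- spec$id_offset
    rand_label <- function() {
      paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), replace = TRUE),
            collapse = "")
    }
    ids <- integer(0)
    labels <- character(0)
    new_node <- function() {
      id <- off + length(ids) + 1L
      ids <<- c(ids, id)
      labels[as.character(id)] <<- rand_label()
      id
    }
    edges_id <- matrix(integer(0), ncol = 2L)
    add_edge <- function(u, v) edges_id <<- rbind(edges_id, c(u, v))
    prev <- new_node()
    start <- prev
    while (length(ids) + 3L <= spec$n_ids) {
      if (runif(1) < spec$bubble_density) {
        x <- new_node(); y <- new_node(); z <- new_node()
        add_edge(prev, x); add_edge(prev, y)
        add_edge(x, z); add_edge(y, z)
        prev <- z
      } else {
        n <- new_node()
        add_edge(prev, n)
        prev <- n
      }
    }
    if (nrow(edges_id) == 0L) {  # degenerate: ensure at least one edge
      n <- new_node()
      add_edge(prev, n)
    }
    if (spec$cycles && length(ids) >= 4L) {
      a <- ids[2L]
      b <- ids[length(ids) - 1L]
      add_edge(b, a)  # back edge: cycle
    }
    edges <- cbind(node_encode(edges_id[, 1L]), node_encode(edges_id[, 2L]))
    graph <- bd_graph(labels, edges)

    # forward adjacency over oriented forward nodes, successors sorted
    adj <- split(node_encode(edges_id[, 2L]), node_encode(edges_id[, 1L]))
    adj <- lapply(adj, sort)
    founder_walk <- function(pick_last) {
      v <- node_encode(start)
      out <- v
      visits <- 0L
      while (!is.null(adj[[as.character(v)]]) && visits < 4L * length(ids)) {
        nxt <- adj[[as.character(v)]]
        # founders never take back edges (targets already visited)
        nxt <- nxt[!(nxt %in% out)]
        if (length(nxt) == 0L) break
        v <- if (pick_last) nxt[length(nxt)] else nxt[1L]
        out <- c(out, v)
        visits <- visits + 1L
      }
      out
    }
    founders <- list(founder_walk(FALSE), founder_walk(TRUE))
    gen_walk <- function() {
      f <- sample(1:2, 1)
      v <- node_encode(start)
      out <- v
      steps <- 0L
      while (length(out) < spec$max_len && steps < 4L * spec$max_len) {
        steps <- steps + 1L
        nxt <- adj[[as.character(v)]]
        if (is.null(nxt) || length(nxt) == 0L) break
        if (length(nxt) > 1L && runif(1) < spec$recomb) f <- 3L - f
        cand <- nxt
        if (spec$recomb > 0 && spec$cycles) {
          # may revisit through the back edge
          take_back <- cand[cand %in% out]
          if (length(take_back) && runif(1) < 0.3 &&
              sum(out %in% take_back[1L]) < 2L) {
            v <- take_back[1L]
            out <- c(out, v)
            next
          }
        }
        cand <- cand[!(cand %in% out) | spec$cycles]
        if (length(cand) == 0L) break
        v <- if (length(cand) == 1L) cand else
          if (f == 1L) cand[1L] else cand[length(cand)]
        out <- c(out, v)
      }
      out
    }
    paths <- vector("list", spec$n_paths)
    for (j in seq_len(spec$n_paths)) {
      if (j > 1L && runif(1) < 0.15) {
        paths[[j]] <- paths[[sample(j - 1L, 1)]]  # duplicate path
      } else if (spec$recomb > 0 && runif(1) < 0.1) {
        w <- gen_walk()
        s <- sample(length(w), 1)
        l <- sample(length(w) - s + 1L, 1)
        paths[[j]] <- w[s:(s + l - 1L)]  # sub-walk, possibly a single node
      } else {
        paths[[j]] <- if (spec$recomb == 0) founders[[sample(1:2, 1)]] else
          gen_walk()
      }
    }
    list(graph = graph, paths = paths)
  })
}

# ---- Brute-force oracle ----------------------------------------------------

#' Brute-force GBWT oracle by reverse-prefix sorting
#'
#' Enumerates every occurrence of every sequence (the occurrence of node
#' `P[i]` at offset `i`, plus one end-marker occurrence per sequence), sorts
#' them by the reversed prefix `(P[i], P[i-1], ..., P[0], $_j)` with the
#' distinct end-markers `$_j < $_{j+1}` breaking ties by sequence id, and
#' partitions the sorted list into per-node record views. This is the ground
#' truth the compiled index is tested against.
#'
#' @param paths List of integer vectors: the exact sequences to index (the
#'   caller supplies reverse paths itself when indexing both orientations).
#' @return A list with `occ` (data.frame `node`, `path`, `offset`,
#'   `successor` in global sorted order; `offset` is -1 for end-marker
#'   occurrences), `da` (the document array: `occ$path`), `records` (named
#'   by node value: `header` data.frame `successor`, `rank`; `runs`
#'   data.frame `successor`, `length`; `ids` per-record document array) and
#'   `n_paths`.
#' @export
naive_gbwt <- function(paths) {
  m <- length(paths)
  lens <- lengths(paths)
  stopifnot(all(lens > 0L))
  total <- sum(lens) + m
  maxk <- max(lens) + 1L
  pad <- -(m + 1L)
  key <- matrix(pad, nrow = total, ncol = maxk)
  node <- integer(total)
  pathid <- integer(total)
  offset <- integer(total)
  successor <- integer(total)
  r <- 0L
  for (j in seq_len(m)) {
    p <- paths[[j]]
    n <- length(p)
    # end-marker occurrence: key ($_j), successor = first node
    r <- r + 1L
    key[r, 1L] <- j - 1L - m
    node[r] <- 0L
    pathid[r] <- j - 1L
    offset[r] <- -1L
    successor[r] <- p[1L]
    for (i in seq_len(n)) {
      r <- r + 1L
      k <- c(rev(p[seq_len(i)]), j - 1L - m)
      key[r, seq_along(k)] <- k
      node[r] <- p[i]
      pathid[r] <- j - 1L
      offset[r] <- i - 1L
      successor[r] <- if (i < n) p[i + 1L] else 0L
    }
  }
  ord <- do.call(order, lapply(seq_len(maxk), function(cc) key[, cc]))
  occ <- data.frame(node = node[ord], path = pathid[ord],
                    offset = offset[ord], successor = successor[ord])
  # cumulative ranks: occurrences of w in records with node value < v
  records <- list()
  nodes <- sort(unique(occ$node))
  tot <- integer(0)  # named running totals per successor
  for (v in nodes) {
    sub <- occ[occ$node == v, , drop = FALSE]
    succs <- sort(unique(sub$successor))
    rank <- vapply(succs, function(w) {
      t <- tot[as.character(w)]
      if (is.na(t)) 0L else as.integer(t)
    }, integer(1))
    rl <- rle(sub$successor)
    records[[as.character(v)]] <- list(
      header = data.frame(successor = succs, rank = rank),
      runs = data.frame(successor = rl$values, length = rl$lengths),
      ids = sub$path)
    cnt <- table(sub$successor)
    for (w in names(cnt)) {
      tot[w] <- (if (is.na(tot[w])) 0L else tot[w]) + as.integer(cnt[[w]])
    }
  }
  list(occ = occ, da = occ$path, records = records, n_paths = m)
}

#' Brute-force subpath count
#'
#' @param paths List of integer vectors.
#' @param x Non-empty pattern (integer vector of oriented node values).
#' @return Number of occurrences of `x` as a contiguous subpath.
#' @export
naive_find <- function(paths, x) {
  stopifnot(length(x) > 0L)
  k <- length(x)
  sum(vapply(paths, function(p) {
    n <- length(p)
    if (n < k) return(0L)
    sum(vapply(seq_len(n - k + 1L),
               function(s) all(p[s:(s + k - 1L)] == x), logical(1)))
  }, integer(1)))
}

#' Brute-force locate: containing sequence ids, one per occurrence
#'
#' @param paths List of integer vectors.
#' @param x Non-empty pattern.
#' @return Integer vector of 0-based sequence ids (multiset, sorted).
#' @export
naive_locate <- function(paths, x) {
  k <- length(x)
  out <- integer(0)
  for (j in seq_along(paths)) {
    p <- paths[[j]]
    n <- length(p)
    if (n < k) next
    hits <- sum(vapply(seq_len(n - k + 1L),
                       function(s) all(p[s:(s + k - 1L)] == x), logical(1)))
    out <- c(out, rep(j - 1L, hits))
  }
  sort(out)
}

#' Table of all occurring subpaths up to a length
#'
#' One pass over all sequences; used to drive exhaustive query checks
#' without rescanning per pattern.
#'
#' @param paths List of integer vectors.
#' @param max_len Maximum subpath length.
#' @return A named list keyed by comma-joined pattern; each element has
#'   `pattern`, `count` and `ids` (sorted multiset of sequence ids).
#' @export
naive_subpath_table <- function(paths, max_len = 5L) {
  acc <- new.env(parent = emptyenv())
  for (j in seq_along(paths)) {
    p <- paths[[j]]
    n <- length(p)
    for (L in seq_len(min(max_len, n))) {
      for (s in seq_len(n - L + 1L)) {
        pat <- p[s:(s + L - 1L)]
        kk <- paste(pat, collapse = ",")
        cur <- acc[[kk]]
        if (is.null(cur)) {
          acc[[kk]] <- list(pattern = pat, count = 1L, ids = j - 1L)
        } else {
          cur$count <- cur$count + 1L
          cur$ids <- c(cur$ids, j - 1L)
          acc[[kk]] <- cur
        }
      }
    }
  }
  out <- as.list(acc)
  lapply(out, function(e) {
    e$ids <- sort(e$ids)
    e
  })
}
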