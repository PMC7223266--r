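# Haplotype-aware graph simplification: prune complex regions, decompose
# what was removed into connected components of the complement edge set,
# search the GBWT for the haplotype-supported maximal paths through each
# component, and unfold those paths back into the pruned graph via
# prefix/reverse-suffix tries with node duplication and an id translation
# map. The guarantee: every indexed haplotype path is embeddable in the
# simplified graph, without re-introducing recombinant paths inside a
# component.

#' Pruning parameters
#'
#' @param k Window length in bases over which edge choices are counted
#'   (default 24).
#' @param max_choices Maximum number of edge choices a `k`-base window may
#'   make before its edges are removed (default 3).
#' @param min_component_bp Weakly connected components with less total
#'   sequence than this are deleted (default 33).
#' @param restore_reference Add reference path nodes and edges back after
#'   pruning.
#' @return A `prune_params` list.
#' @export
prune_params <- function(k = 24L, max_choices = 3L, min_component_bp = 33L,
                         restore_reference = FALSE) {
  stopifnot(k >= 1L, max_choices >= 0L)
  list(k = as.integer(k), max_choices = as.integer(max_choices),
       min_component_bp = as.integer(min_component_bp),
       restore_reference = isTRUE(restore_reference))
}

edge_key <- function(e) paste(e[, 1L], e[, 2L])

oriented_adjacency <- function(edges) {
  out <- split(edges[, 2L], edges[, 1L])
  lapply(out, sort)
}

#' Prune complex regions from a graph
#'
#' Removes every edge whose best `k`-base window (a walk of at least `k`
#' bases through the edge, truncated at graph boundaries) still makes more
#' than `max_choices` edge choices. Traversing an edge counts as a choice
#' when its source has out-degree >= 2 or its target has in-degree >= 2;
#' forced edges (sole outgoing and sole incoming) are never removed. Weakly
#' connected components with total label length below `min_component_bp`
#' are then deleted, and reference paths are optionally restored.
#'
#' @param graph A `bdgraph`.
#' @param params A [prune_params()] list.
#' @return The pruned `bdgraph`.
#' @export
prune <- function(graph, params = prune_params()) {
  e <- graph$edges
  if (nrow(e) == 0L) return(graph)
  lab_len <- nchar(graph$labels)
  len_of <- function(v) unname(lab_len[as.character(v %/% 2L)])
  outdeg <- table(e[, 1L])
  indeg <- table(e[, 2L])
  deg <- function(tb, v) {
    x <- tb[as.character(v)]
    ifelse(is.na(x), 0L, as.integer(x))
  }
  cost <- (deg(outdeg, e[, 1L]) >= 2L) | (deg(indeg, e[, 2L]) >= 2L)
  forced <- (deg(outdeg, e[, 1L]) == 1L) & (deg(indeg, e[, 2L]) == 1L)
  out_adj <- split(seq_len(nrow(e)), e[, 1L])   # edge indices by source
  in_adj <- split(seq_len(nrow(e)), e[, 2L])    # edge indices by target
  k <- params$k
  # A window through edge (u, v) is a walk containing it with >= k bases,
  # or an inextensible walk with fewer. Four DP tables over (oriented node,
  # remaining bases), all with remaining <= k so label lengths >= 1 keep the
  # recursion acyclic:
  #   fwd/bwd(v, b): min choices of a walk covering >= b bases (Inf when no
  #     walk is long enough);
  #   tfwd/tbwd(v): dead-ended walks, as min choices per capped base count.
  fmemo <- new.env(parent = emptyenv())
  bmemo <- new.env(parent = emptyenv())
  tfmemo <- new.env(parent = emptyenv())
  tbmemo <- new.env(parent = emptyenv())
  dp_reach <- function(v, b, adj, endpoint, memo) {
    if (b <= len_of(v)) return(0)
    key <- paste(v, b)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    es <- adj[[as.character(v)]]
    best <- Inf
    for (ei in es) {
      best <- min(best, cost[ei] +
                    dp_reach(e[ei, endpoint], b - len_of(v), adj, endpoint,
                             memo))
    }
    memo[[key]] <- best
    best
  }
  fwd <- function(v, b) dp_reach(v, b, out_adj, 2L, fmemo)
  bwd <- function(v, b) dp_reach(v, b, in_adj, 1L, bmemo)
  # dead-ended walk tables can cycle; walks are restricted to node-simple
  # continuations via an in-progress guard (a deterministic under-
  # approximation that only keeps more edges)
  trunc_guard <- new.env(parent = emptyenv())
  dp_trunc <- function(v, adj, endpoint, memo) {
    key <- as.character(v)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (!is.null(trunc_guard[[key]])) return(rep(Inf, k + 1L))
    trunc_guard[[key]] <- TRUE
    on.exit(rm(list = key, envir = trunc_guard))
    es <- adj[[key]]
    res <- rep(Inf, k + 1L)  # index = capped bases + 1
    if (is.null(es) || length(es) == 0L) {
      res[min(len_of(v), k) + 1L] <- 0
    } else {
      for (ei in es) {
        sub <- dp_trunc(e[ei, endpoint], adj, endpoint, memo)
        for (t in which(is.finite(sub))) {
          tt <- min(t - 1L + len_of(v), k) + 1L
          res[tt] <- min(res[tt], cost[ei] + sub[t])
        }
      }
    }
    memo[[key]] <- res
    res
  }
  mchoice <- vapply(seq_len(nrow(e)), function(ei) {
    u <- e[ei, 1L]
    v <- e[ei, 2L]
    if (k <= 1L) return(cost[ei] + 0)
    best <- Inf
    tb <- dp_trunc(u, in_adj, 1L, tbmemo)
    tf <- dp_trunc(v, out_adj, 2L, tfmemo)
    for (a in 1:(k - 1L)) {
      b <- k - a
      best <- min(best,
                  bwd(u, a) + fwd(v, b),          # full k-base window
                  if (is.finite(tb[a + 1L])) tb[a + 1L] + fwd(v, b) else Inf,
                  if (is.finite(tf[b + 1L])) bwd(u, a) + tf[b + 1L] else Inf)
      if (best == 0) break
    }
    # inextensible walk shorter than k bases
    for (a in which(is.finite(tb)) - 1L) {
      for (b in which(is.finite(tf)) - 1L) {
        if (a + b < k) best <- min(best, tb[a + 1L] + tf[b + 1L])
      }
    }
    cost[ei] + best
  }, numeric(1))
  drop <- (mchoice > params$max_choices) & !forced
  # removal decisions are symmetric by construction; enforce anyway
  mirror <- paste(node_reverse(e[, 2L]), node_reverse(e[, 1L]))
  drop <- drop | drop[match(mirror, edge_key(e))]
  kept <- e[!drop, , drop = FALSE]
  # delete weakly connected components with too little sequence
  ids <- as.integer(names(graph$labels))
  comp <- weak_components(ids, kept)
  keep_ids <- unlist(lapply(comp, function(cc) {
    if (sum(lab_len[as.character(cc)]) >= params$min_component_bp) cc
    else NULL
  }))
  if (params$restore_reference && length(graph$reference_paths)) {
    for (p in graph$reference_paths) {
      keep_ids <- union(keep_ids, p %/% 2L)
      if (length(p) > 1L) {
        kept <- rbind(kept, cbind(p[-length(p)], p[-1L]))
      }
    }
  }
  keep_ids <- sort(keep_ids)
  kept <- kept[(kept[, 1L] %/% 2L) %in% keep_ids &
                 (kept[, 2L] %/% 2L) %in% keep_ids, , drop = FALSE]
  bd_graph(graph$labels[as.character(keep_ids)], kept,
           reference_paths = graph$reference_paths)
}

weak_components <- function(ids, edges) {
  parent <- seq_along(ids)
  names(parent) <- as.character(ids)
  findp <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    a <- match(as.character(edges[, 1L] %/% 2L), as.character(ids))
    b <- match(as.character(edges[, 2L] %/% 2L), as.character(ids))
    for (r in seq_len(nrow(edges))) {
      ra <- findp(a[r])
      rb <- findp(b[r])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(ids), findp, integer(1))
  unname(split(ids, roots))
}

#' Graph induced by the paths of a GBWT index
#'
#' @param graph The original `bdgraph` (provides labels).
#' @param index A `gbwt` over the graph.
#' @return A `bdgraph` containing exactly the nodes and edges used by the
#'   indexed paths.
#' @export
induced_graph <- function(graph, index) {
  n <- gbwt_n_sequences(index)
  edges <- matrix(integer(0), ncol = 2L)
  used <- integer(0)
  for (j in seq_len(n) - 1L) {
    p <- gbwt_extract(index, j)
    used <- union(used, p %/% 2L)
    if (length(p) > 1L) edges <- rbind(edges, cbind(p[-length(p)], p[-1L]))
  }
  bd_graph(graph$labels[as.character(sort(used))], edges,
           reference_paths = graph$reference_paths)
}

#' Connected components of the complement edge set
#'
#' The complement edges are those used by GBWT paths but absent from the
#' pruned graph. Each weakly connected component of the complement is a
#' removed region; its border is the set of component nodes that still
#' exist in the pruned graph, the rest are internal.
#'
#' @param gi Graph induced by GBWT paths (see [induced_graph()]).
#' @param gp The pruned graph.
#' @return A list of components ordered by smallest node id, each with
#'   `ids`, `edges` (oriented, symmetric), `border` and `internal` id sets.
#' @export
complement_components <- function(gi, gp) {
  comp_edges <- gi$edges[!(edge_key(gi$edges) %in% edge_key(gp$edges)), ,
                         drop = FALSE]
  if (nrow(comp_edges) == 0L) return(list())
  ids <- sort(unique(as.vector(comp_edges) %/% 2L))
  comps <- weak_components(ids, comp_edges)
  comps <- comps[vapply(comps, length, integer(1)) > 0L]
  comps <- comps[order(vapply(comps, min, integer(1)))]
  vp <- as.integer(names(gp$labels))
  lapply(comps, function(cc) {
    cc <- sort(cc)
    sel <- (comp_edges[, 1L] %/% 2L) %in% cc & (comp_edges[, 2L] %/% 2L) %in% cc
    list(ids = cc, edges = comp_edges[sel, , drop = FALSE],
         border = intersect(cc, vp), internal = setdiff(cc, vp))
  })
}

#' Haplotype-supported maximal paths through a pruned component
#'
#' Searches the GBWT along the component's edges. A search starts from each
#' oriented border node with the full record range, and from each oriented
#' internal node with the start-of-path range. A path of length >= 2 is
#' maximal when it reaches a border node again (output only if it also
#' started at one) or when no extension is supported. Dead-end paths are
#' optionally extended along reference paths; every output is canonicalized
#' to the lexicographically smaller of itself and its reverse, and
#' de-duplicated.
#'
#' @param comp A component from [complement_components()].
#' @param index A `gbwt` built with both orientations.
#' @param reference_paths Named list of reference paths for dead-end
#'   extension (may be empty).
#' @return List of maximal paths (integer vectors).
#' @export
find_maximal_paths <- function(comp, index, reference_paths = list()) {
  if (gbwt_n_sequences(index) == 0L) return(list())
  adj <- oriented_adjacency(comp$edges)
  is_border <- function(v) (v %/% 2L) %in% comp$border
  n_seq <- gbwt_n_sequences(index)
  start_state <- function(v, internal) {
    if (internal) {
      gbwt_extend(index, gbwt_state(0L, 0L, n_seq - 1L), v)
    } else {
      gbwt_find(index, v)
    }
  }
  stack <- list()
  for (id in comp$ids) {
    for (v in c(node_encode(id), node_encode(id, TRUE))) {
      s <- start_state(v, !(id %in% comp$border))
      if (state_size(s) > 0L) stack[[length(stack) + 1L]] <- list(X = v, s = s)
    }
  }
  out <- list()
  emit <- function(X) out[[length(out) + 1L]] <<- X
  while (length(stack)) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    X <- st$X
    x <- X[length(X)]
    if (length(X) >= 2L && is_border(x)) {
      if (is_border(X[1L])) emit(X)
      next
    }
    extended <- FALSE
    for (w in adj[[as.character(x)]]) {
      s2 <- gbwt_extend(index, st$s, w)
      if (state_size(s2) > 0L) {
        stack[[length(stack) + 1L]] <- list(X = c(X, w), s = s2)
        extended <- TRUE
      }
    }
    if (!extended && length(X) >= 2L) emit(X)
  }
  # reference extension of non border-to-border paths
  out <- lapply(out, function(P) {
    if (is_border(P[1L]) && is_border(P[length(P)])) return(P)
    Q <- canonical_path(P)
    Q <- ref_extend(Q, comp, reference_paths, is_border)
    Q
  })
  out <- lapply(out, canonical_path)
  out[!duplicated(vapply(out, paste, character(1), collapse = ","))]
}

canonical_path <- function(P) {
  R <- reverse_path(P)
  n <- length(P)
  for (i in seq_len(n)) {
    if (P[i] < R[i]) return(P)
    if (P[i] > R[i]) return(R)
  }
  P
}

# extend the dead ends of Q along the smallest-named reference path that
# carries them, staying inside the component, until a border node is met
ref_extend <- function(Q, comp, reference_paths, is_border) {
  if (length(reference_paths) == 0L) return(Q)
  nms <- sort(names(reference_paths))
  ext_forward <- function(Q) {
    v <- Q[length(Q)]
    if (is_border(v)) return(Q)
    for (nm in nms) {
      rp <- reference_paths[[nm]]
      hit <- which(rp == v)
      if (length(hit) == 0L) {
        rp <- reverse_path(rp)
        hit <- which(rp == v)
      }
      if (length(hit) == 0L) next
      i <- hit[1L]
      while (i < length(rp)) {
        nxt <- rp[i + 1L]
        if (!((nxt %/% 2L) %in% comp$ids)) break
        Q <- c(Q, nxt)
        i <- i + 1L
        if (is_border(nxt)) break
      }
      break
    }
    Q
  }
  Q <- ext_forward(Q)
  Q <- reverse_path(ext_forward(reverse_path(Q)))
  Q
}

#' Unfold maximal paths into a pruned graph
#'
#' Each maximal path is split into a prefix of length `ceiling(|P| / 2)`
#' and the remaining suffix. A trie of the prefixes and a trie of the
#' reversed suffixes are built; every trie edge becomes a node of the
#' unfolded component (border nodes at trie depth 1 are reused from the
#' pruned graph, all other trie edges become fresh duplicate nodes recorded
#' in the translation mapping), trie adjacency becomes graph edges in path
#' direction, and one cross edge per maximal path connects its prefix end
#' to its suffix start.
#'
#' @param gp The pruned `bdgraph`.
#' @param comp The component being unfolded.
#' @param maximal_paths Canonical maximal paths from [find_maximal_paths()].
#' @param labels Labels of the original graph (for duplicate nodes).
#' @param next_id First free id for duplicates.
#' @return A list with `nodes` (data.frame `new_id`, `orig` signed original
#'   id), `edges` (oriented matrix of added edges, not yet
#'   symmetry-closed), `next_id`.
#' @export
unfold_component <- function(gp, comp, maximal_paths, labels, next_id) {
  trie <- new.env(parent = emptyenv())  # key -> unfolded oriented value
  dup_nodes <- list()
  edges <- matrix(integer(0), ncol = 2L)
  add_edge <- function(u, v) edges <<- rbind(edges, c(u, v))
  get_unfolded <- function(key, v, depth, side) {
    kk <- paste(side, key, sep = "|")
    hit <- trie[[kk]]
    if (!is.null(hit)) return(hit)
    id <- v %/% 2L
    if (depth == 1L && id %in% comp$border) {
      trie[[kk]] <- v  # border node: reuse the original
      return(v)
    }
    d <- next_id
    next_id <<- next_id + 1L
    dup_nodes[[length(dup_nodes) + 1L]] <<-
      data.frame(new_id = d, orig = if (v %% 2L == 1L) -id else id)
    u <- node_encode(d, FALSE)
    trie[[kk]] <- u
    u
  }
  maximal_paths <- maximal_paths[order(vapply(maximal_paths, paste,
                                              character(1), collapse = ","))]
  for (P in maximal_paths) {
    n <- length(P)
    pl <- ceiling(n / 2)
    prefix <- P[seq_len(pl)]
    suffix <- P[(pl + 1L):n]
    # prefix trie: root-to-leaf along the path
    prev <- NULL
    key <- character(0)
    for (i in seq_along(prefix)) {
      key <- c(key, prefix[i])
      u <- get_unfolded(paste(key, collapse = ","), prefix[i], i, "P")
      if (!is.null(prev)) add_edge(prev, u)
      prev <- u
    }
    pref_end <- prev
    # reverse-suffix trie: root edge is the LAST node of the path
    rs <- rev(suffix)
    prev <- NULL
    key <- character(0)
    for (i in seq_along(rs)) {
      key <- c(key, rs[i])
      u <- get_unfolded(paste(key, collapse = ","), rs[i], i, "S")
      if (!is.null(prev)) add_edge(u, prev)  # edge in path direction
      prev <- u
    }
    suf_start <- prev
    add_edge(pref_end, suf_start)  # cross edge prefix -> suffix
  }
  nodes <- if (length(dup_nodes)) do.call(rbind, dup_nodes) else
    data.frame(new_id = integer(0), orig = integer(0))
  list(nodes = nodes, edges = edges[!duplicated(edges), , drop = FALSE],
       next_id = next_id)
}

#' Haplotype-aware graph simplification
#'
#' Prunes the graph (or accepts any externally pruned subgraph), decomposes
#' the removed regions, finds the haplotype-supported maximal paths through
#' each with the GBWT, and unfolds them back with node duplication. The
#' returned graph contains every indexed haplotype path up to translation.
#'
#' @param graph The original `bdgraph`.
#' @param index A `gbwt` over the graph, built with both orientations.
#' @param params [prune_params()] for the built-in pruner.
#' @param pruned Optional pre-pruned `bdgraph` (any pruning algorithm that
#'   removes nodes or edges); overrides `params`.
#' @return A list with `graph` (the simplified `bdgraph`), `mapping` (an
#'   `unfold_mapping`), and `components` (per component: `border`,
#'   `internal`, `maximal_paths`, `added_edges`, `dup_ids`).
#' @export
simplify <- function(graph, index, params = prune_params(), pruned = NULL) {
  gp <- if (is.null(pruned)) prune(graph, params) else pruned
  gi <- induced_graph(graph, index)
  comps <- complement_components(gi, gp)
  all_ids <- as.integer(names(graph$labels))
  next_id <- if (length(all_ids)) max(all_ids) + 1L else 1L
  labels <- gp$labels
  edges <- gp$edges
  map <- integer(0)
  comp_info <- list()
  for (comp in comps) {
    mp <- find_maximal_paths(comp, index, graph$reference_paths)
    uf <- unfold_component(gp, comp, mp, graph$labels, next_id)
    next_id <- uf$next_id
    if (nrow(uf$nodes)) {
      # a duplicate spells, in forward orientation, what its oriented
      # original spells (reverse originals give the reverse complement)
      labels[as.character(uf$nodes$new_id)] <-
        node_label(graph, node_encode(abs(uf$nodes$orig), uf$nodes$orig < 0L))
      map[as.character(uf$nodes$new_id)] <- uf$nodes$orig
    }
    added <- close_symmetry(uf$edges)
    edges <- rbind(edges, added)
    comp_info[[length(comp_info) + 1L]] <-
      list(border = comp$border, internal = comp$internal,
           maximal_paths = mp, added_edges = uf$edges,
           dup_ids = uf$nodes$new_id)
  }
  sg <- bd_graph(labels, edges, reference_paths = graph$reference_paths)
  mapping <- structure(list(map = map, original_ids = all_ids),
                       class = "unfold_mapping")
  list(graph = sg, mapping = mapping, components = comp_info)
}

#' Translate a path of the simplified graph back to original ids
#'
#' Duplicate nodes are substituted by their original oriented nodes
#' (orientation composed); original nodes map to themselves. Translation is
#' a graph homomorphism onto the original graph and commutes with path
#' reversal.
#'
#' @param mapping An `unfold_mapping` from [simplify()].
#' @param path Integer vector of oriented node values in the simplified
#'   graph.
#' @return The translated path over original oriented nodes.
#' @export
translate <- function(mapping, path) {
  if (length(path) == 0L) return(integer(0))
  vapply(path, function(v) {
    id <- v %/% 2L
    m <- mapping$map[as.character(id)]
    if (!is.na(m)) {
      ov <- node_encode(abs(m), m < 0L)
      if (v %% 2L == 1L) ov <- node_reverse(ov)
      return(ov)
    }
    if (!(id %in% mapping$original_ids)) {
      stop("node ", id, " is neither a duplicate nor an original node",
           call. = FALSE)
    }
    as.integer(v)
  }, integer(1))
}

#' Is a path embeddable in a graph under a translation?
#'
#' Checks whether some path of `graph` translates node-wise to `path`.
#'
#' @param graph The simplified `bdgraph`.
#' @param mapping The `unfold_mapping`.
#' @param path A path over original oriented nodes.
#' @return `TRUE` or `FALSE`.
#' @export
path_embeddable <- function(graph, mapping, path) {
  if (length(path) == 0L) return(TRUE)
  # all simplified oriented nodes translating to a given original node
  ids <- as.integer(names(graph$labels))
  cand_of <- function(target) {
    hits <- integer(0)
    tid <- target %/% 2L
    if (tid %in% ids) hits <- c(hits, target)
    dup <- mapping$map
    if (length(dup)) {
      sel <- abs(dup) == tid
      for (d in as.integer(names(dup)[sel])) {
        if (!(d %in% ids)) next
        fwd_val <- node_encode(abs(dup[as.character(d)]),
                               dup[as.character(d)] < 0L)
        hits <- c(hits, node_encode(d, fwd_val != target))
      }
    }
    hits
  }
  cur <- cand_of(path[1L])
  if (length(cur) == 0L) return(FALSE)
  if (length(path) == 1L) return(TRUE)
  ek <- edge_key(graph$edges)
  for (i in 2:length(path)) {
    nxt <- cand_of(path[i])
    nxt <- nxt[vapply(nxt, function(w) {
      any(paste(cur, w) %in% ek)
    }, logical(1))]
    if (length(nxt) == 0L) return(FALSE)
    cur <- nxt
  }
  TRUE
}

#' All k-base substrings spelled by walks of a graph
#'
#' Enumerates, for every oriented start node, the walks long enough to
#' cover `k` bases from each start offset inside the node, and collects the
#' spelled k-mers. Intended for small graphs (fixture scale).
#'
#' @param graph A `bdgraph`.
#' @param k k-mer length in bases.
#' @return Character vector of distinct k-mers.
#' @export
spelled_kmers <- function(graph, k) {
  adj <- oriented_adjacency(graph$edges)
  acc <- new.env(parent = emptyenv())
  ids <- as.integer(names(graph$labels))
  starts <- c(node_encode(ids), node_encode(ids, TRUE))
  walk <- function(v, s, need) {
    s <- paste0(s, node_label(graph, v))
    if (nchar(s) >= need || is.null(adj[[as.character(v)]])) {
      first_len <- need - k + 1L
      if (nchar(s) >= k) {
        for (o in seq_len(min(first_len, nchar(s) - k + 1L))) {
          acc[[substr(s, o, o + k - 1L)]] <- TRUE
        }
      }
      if (nchar(s) >= need) return(invisible(NULL))
    }
    for (w in adj[[as.character(v)]]) walk(w, s, need)
    invisible(NULL)
  }
  for (v in starts) {
    need <- nchar(node_label(graph, v)) + k - 1L
    walk(v, "", need)
  }
  ls(acc)
}

#' k-mers of a string
#' @param s A string.
#' @param k k-mer length.
#' @return Character vector of distinct k-mers (empty when `nchar(s) < k`).
#' @export
sequence_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}
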