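#' @useDynLib graphbwt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- Oriented nodes --------------------------------------------------------
#
# A bidirected variation graph is simulated as a directed graph over oriented
# nodes. The forward orientation of graph id n encodes to the integer 2n, the
# reverse orientation to 2n + 1, and 0 is reserved for the end-marker. This
# gives a total order with the end-marker smallest and keeps node values a
# dense subset of an integer range.

#' Encode graph ids as oriented node values
#'
#' @param id Integer vector of graph node ids (all >= 1).
#' @param reverse Logical vector (recycled): `TRUE` for the reverse
#'   orientation.
#' @return Integer vector of oriented node values (`2 * id + reverse`).
#' @examples
#' node_encode(1)            # 2
#' node_encode(1, TRUE)      # 3
#' @export
node_encode <- function(id, reverse = FALSE) {
  id <- as.integer(id)
  if (any(is.na(id)) || any(id < 1L)) {
    stop("graph ids must be positive integers", call. = FALSE)
  }
  as.integer(2L * id + as.logical(reverse))
}

#' Decode oriented node values
#'
#' @param v Integer vector of oriented node values (all > 0).
#' @return A data.frame with columns `id` and `reverse`.
#' @export
node_decode <- function(v) {
  v <- as.integer(v)
  if (any(is.na(v)) || any(v <= 1L)) {
    stop("oriented node values must be > 1 (0 is the end-marker)", call. = FALSE)
  }
  data.frame(id = v %/% 2L, reverse = (v %% 2L) == 1L)
}

#' Flip the orientation of oriented nodes
#'
#' The end-marker 0 has no reverse; passing it is an error.
#'
#' @param v Integer vector of oriented node values (all > 0).
#' @return Integer vector with the orientation bit flipped.
#' @export
node_reverse <- function(v) {
  v <- as.integer(v)
  if (any(is.na(v)) || any(v <= 0L)) {
    stop("cannot reverse the end-marker", call. = FALSE)
  }
  as.integer(bitwXor(v, 1L))
}

#' Reverse a path
#'
#' Returns the reverse path: the reverse orientation of each node, in
#' reversed order. `reverse_path(reverse_path(P))` is the identity.
#'
#' @param path Integer vector of oriented node values (non-empty, all > 0).
#' @return Integer vector, the reverse path.
#' @export
reverse_path <- function(path) {
  if (length(path) == 0L) stop("cannot reverse an empty path", call. = FALSE)
  rev(node_reverse(path))
}

# ---- Bidirected graphs -----------------------------------------------------

#' Construct a bidirected variation graph
#'
#' Nodes carry DNA labels; edges are ordered pairs of oriented node values
#' and are closed under the bidirected symmetry (u, v) <=> (rev(v), rev(u)).
#'
#' @param labels Character vector of node labels; names are graph ids.
#'   Unnamed labels get ids `1..length(labels)`.
#' @param edges Two-column integer matrix of oriented node values (may have
#'   zero rows). The symmetry closure is applied.
#' @param reference_paths Optional named list of paths (integer vectors of
#'   oriented node values).
#' @return An object of class `bdgraph` with elements `labels`, `edges`,
#'   `reference_paths`.
#' @export
bd_graph <- function(labels, edges = NULL, reference_paths = list()) {
  nms <- names(labels)
  labels <- as.character(labels)
  names(labels) <- if (is.null(nms)) as.character(seq_along(labels)) else nms
  if (any(!nzchar(labels))) stop("node labels must be non-empty", call. = FALSE)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
  }
  edges <- close_symmetry(edges)
  ids <- as.integer(names(labels))
  eids <- unique(as.vector(edges) %/% 2L)
  if (length(eids) && !all(eids %in% ids)) {
    stop("edge endpoint without a label entry: id ",
         paste(setdiff(eids, ids), collapse = ", "), call. = FALSE)
  }
  g <- list(labels = labels, edges = edges, reference_paths = reference_paths)
  class(g) <- "bdgraph"
  g
}

#' @method print bdgraph
#' @export
print.bdgraph <- function(x, ...) {
  cat(sprintf("bidirected graph: %d nodes, %d directed edges, %d reference path(s)\n",
              length(x$labels), nrow(x$edges), length(x$reference_paths)))
  invisible(x)
}

#' Symmetry-close an oriented edge set
#'
#' Adds the companion edge (rev(v), rev(u)) for every edge (u, v),
#' de-duplicates and sorts. Idempotent.
#'
#' @param edges Two-column integer matrix of oriented node values.
#' @return The closed, de-duplicated, sorted edge matrix.
#' @export
close_symmetry <- function(edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) == 0L) return(edges)
  comp <- cbind(node_reverse(edges[, 2L]), node_reverse(edges[, 1L]))
  all <- rbind(edges, comp)
  all <- all[!duplicated(all), , drop = FALSE]
  all[order(all[, 1L], all[, 2L]), , drop = FALSE]
}

#' Test whether a node sequence is a path of a graph
#'
#' @param graph A `bdgraph`.
#' @param path Integer vector of oriented node values. The empty path is a
#'   path by convention.
#' @return `TRUE` iff every consecutive pair is an edge of the graph.
#' @export
is_path <- function(graph, path) {
  if (length(path) <= 1L) {
    if (length(path) == 1L) {
      return((path %/% 2L) %in% as.integer(names(graph$labels)))
    }
    return(TRUE)
  }
  key <- paste(graph$edges[, 1L], graph$edges[, 2L])
  all(paste(path[-length(path)], path[-1L]) %in% key)
}

#' Label spelled by an oriented node
#'
#' Reverse orientation spells the reverse complement of the node label.
#'
#' @param graph A `bdgraph`.
#' @param v Integer vector of oriented node values.
#' @return Character vector of spelled labels.
#' @export
node_label <- function(graph, v) {
  dec <- node_decode(v)
  lab <- unname(graph$labels[as.character(dec$id)])
  if (any(is.na(lab))) stop("node id without a label", call. = FALSE)
  rc <- dec$reverse
  if (any(rc)) lab[rc] <- vapply(lab[rc], revcomp_dna, character(1))
  lab
}

#' Sequence spelled by a path
#'
#' @param graph A `bdgraph`.
#' @param path Integer vector of oriented node values.
#' @return A single string, the concatenated labels.
#' @export
path_sequence <- function(graph, path) {
  if (length(path) == 0L) return("")
  paste(node_label(graph, path), collapse = "")
}

revcomp_dna <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# ---- GFA1 and plain path files --------------------------------------------

#' Read a GFA1 file
#'
#' Supports S lines (id + sequence), L lines with +/- orientations and 0M
#' overlap, and P lines for named paths. Any other overlap is rejected as an
#' unsupported dialect.
#'
#' @param file Path to a GFA1 file, or a character vector of lines.
#' @return A list with elements `graph` (a `bdgraph`) and `paths` (named list
#'   of oriented node vectors parsed from P lines).
#' @export
read_gfa <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  lines <- lines[nzchar(lines)]
  tags <- substr(lines, 1L, 1L)
  labels <- character(0)
  seen <- character(0)
  for (ln in lines[tags == "S"]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed S line: ", ln, call. = FALSE)
    if (f[2] %in% seen) stop("duplicate segment id: ", f[2], call. = FALSE)
    seen <- c(seen, f[2])
    labels[f[2]] <- f[3]
  }
  edges <- matrix(integer(0), ncol = 2L)
  for (ln in lines[tags == "L"]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) stop("malformed L line: ", ln, call. = FALSE)
    if (f[6] != "0M") stop("unsupported dialect: overlap ", f[6], call. = FALSE)
    u <- node_encode(as.integer(f[2]), f[3] == "-")
    v <- node_encode(as.integer(f[4]), f[5] == "-")
    edges <- rbind(edges, c(u, v))
  }
  paths <- list()
  for (ln in lines[tags == "P"]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed P line: ", ln, call. = FALSE)
    steps <- strsplit(f[3], ",", fixed = TRUE)[[1]]
    ids <- as.integer(sub("[+-]$", "", steps))
    revs <- grepl("-$", steps)
    if (!all(as.character(ids) %in% names(labels))) {
      stop("P line references missing segment in path ", f[2], call. = FALSE)
    }
    paths[[f[2]]] <- node_encode(ids, revs)
  }
  bad <- setdiff(unique(as.character(as.vector(edges) %/% 2L)), names(labels))
  if (length(bad)) stop("L line references missing segment id: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  list(graph = bd_graph(labels, edges, reference_paths = paths), paths = paths)
}

#' Write a GFA1 file
#'
#' Deterministic canonical output: S lines in ascending id order, then L
#' lines (one per unordered bidirected edge, canonical orientation), then P
#' lines in name order.
#'
#' @param graph A `bdgraph`.
#' @param paths Named list of paths to emit as P lines (defaults to the
#'   graph's reference paths).
#' @param file Output path, or `NULL` to return the lines.
#' @return The lines, invisibly when written to a file.
#' @export
write_gfa <- function(graph, paths = graph$reference_paths, file = NULL) {
  ids <- sort(as.integer(names(graph$labels)))
  out <- c("H\tVN:Z:1.0",
           sprintf("S\t%d\t%s", ids, unname(graph$labels[as.character(ids)])))
  e <- graph$edges
  if (nrow(e)) {
    # one line per symmetric pair: keep the lexicographically smaller member
    comp <- cbind(node_reverse(e[, 2L]), node_reverse(e[, 1L]))
    keep <- (e[, 1L] < comp[, 1L]) | (e[, 1L] == comp[, 1L] & e[, 2L] <= comp[, 2L])
    e <- e[keep, , drop = FALSE]
    e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
    orient <- function(v) ifelse(v %% 2L == 0L, "+", "-")
    out <- c(out, sprintf("L\t%d\t%s\t%d\t%s\t0M",
                          e[, 1L] %/% 2L, orient(e[, 1L]),
                          e[, 2L] %/% 2L, orient(e[, 2L])))
  }
  if (length(paths)) {
    nm <- sort(names(paths))
    steps <- vapply(paths[nm], function(p) {
      paste0(p %/% 2L, ifelse(p %% 2L == 0L, "+", "-"), collapse = ",")
    }, character(1))
    out <- c(out, sprintf("P\t%s\t%s\t*", nm, steps))
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Read a plain path file
#'
#' One path per line, space-separated signed graph ids (negative = reverse
#' orientation); comment lines start with `#`.
#'
#' @param file Path or character vector of lines.
#' @return List of integer vectors of oriented node values.
#' @export
read_paths <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    ids <- as.integer(strsplit(ln, "[[:space:]]+")[[1]])
    node_encode(abs(ids), ids < 0L)
  })
}

#' Write a plain path file
#'
#' @param paths List of integer vectors of oriented node values.
#' @param file Output path, or `NULL` to return the lines.
#' @export
write_paths <- function(paths, file = NULL) {
  out <- vapply(paths, function(p) {
    dec <- node_decode(p)
    paste(ifelse(dec$reverse, -dec$id, dec$id), collapse = " ")
  }, character(1))
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
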