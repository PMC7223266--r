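# Merging indexes over the same graph, fast merging of disjoint-node-id
# indexes (different chromosomes), and path removal. The contract for all
# three is structural build-equivalence over the surviving path lists.

extract_original_paths <- function(index) {
  n <- gbwt_n_sequences(index)
  if (n == 0L) return(list())
  ids <- if (index$both) seq(0L, n - 1L, by = 2L) else seq(0L, n - 1L)
  lapply(ids, function(j) gbwt_extract(index, j))
}

check_compatible <- function(a, b) {
  if (!identical(a$both, b$both)) {
    stop("incompatible indexes: orientation flags differ", call. = FALSE)
  }
  if (!identical(as.integer(a$sample_interval), as.integer(b$sample_interval))) {
    stop("incompatible indexes: sample intervals differ", call. = FALSE)
  }
}

#' Merge two GBWT indexes over the same graph
#'
#' The second index's paths are re-inserted after the first index's paths;
#' identifiers of `b` are offset by the path count of `a` and metadata is
#' concatenated. The result is structurally equal to a single build over the
#' concatenated path lists.
#'
#' @param a,b Two `gbwt` indexes with identical flags.
#' @return The merged `gbwt` index.
#' @export
gbwt_merge <- function(a, b) {
  check_compatible(a, b)
  paths_b <- extract_original_paths(b)
  if (length(paths_b) == 0L) return(a)
  gbwt_insert(a, paths_b, b$metadata)
}

#' Fast merge of indexes with disjoint node sets
#'
#' When the two indexes share no graph nodes (e.g. different chromosomes),
#' their records can simply be reused: the merged index is the union of the
#' records, with the end-marker record of `a` followed by that of `b` (so
#' `a`'s sequences keep their identifiers and `b`'s are offset).
#'
#' @param a,b Two `gbwt` indexes with identical flags and disjoint node sets.
#' @return The merged `gbwt` index.
#' @export
gbwt_merge_fast <- function(a, b) {
  check_compatible(a, b)
  na <- setdiff(a$core$nodes, 0L)
  nb <- setdiff(b$core$nodes, 0L)
  shared <- intersect(na, nb)
  if (length(shared)) {
    stop("node sets are not disjoint: shared node ", min(shared),
         call. = FALSE)
  }
  if (gbwt_n_sequences(a) == 0L) return(b)
  if (gbwt_n_sequences(b) == 0L) return(a)
  runs_of <- function(index) {
    co <- index$core
    lapply(seq_along(co$nodes), function(ri) {
      ki <- (co$run_ptr[ri] + 1L):co$run_ptr[ri + 1L]
      list(succ = co$run_succ[ki], len = co$run_len[ki])
    })
  }
  ra <- runs_of(a)
  rb <- runs_of(b)
  names(ra) <- as.character(a$core$nodes)
  names(rb) <- as.character(b$core$nodes)
  # end-marker record: a's body first, then b's
  r0 <- list(succ = c(ra[["0"]]$succ, rb[["0"]]$succ),
             len = c(ra[["0"]]$len, rb[["0"]]$len))
  ra[["0"]] <- NULL
  rb[["0"]] <- NULL
  merged <- c(list(`0` = r0), ra, rb)
  nodes <- sort(as.integer(names(merged)))
  merged <- merged[as.character(nodes)]
  core <- gbwt_from_runs_cpp(nodes,
                             lapply(merged, `[[`, "succ"),
                             lapply(merged, `[[`, "len"),
                             a$sample_interval)
  md <- a$metadata
  if (!is.null(b$metadata)) {
    md <- if (is.null(md)) b$metadata else rbind(md, b$metadata)
  }
  new_gbwt(core, a$sample_interval, a$both, md)
}

#' Remove paths from a GBWT index
#'
#' Remaining paths keep their relative order and are renumbered
#' consecutively; the result is structurally equal to a build over the
#' remaining paths. With both orientations, removing a path removes its
#' reverse companion as well (`ids` are path identifiers, not sequence
#' identifiers).
#'
#' @param index A `gbwt` index.
#' @param ids Integer vector of path identifiers to remove (0-based).
#' @return The reduced `gbwt` index.
#' @export
gbwt_remove <- function(index, ids) {
  ids <- unique(as.integer(ids))
  npaths <- gbwt_stats(index)$paths
  if (length(ids) && (any(ids < 0L) || any(ids >= npaths))) {
    stop("unknown path identifier: ",
         paste(ids[ids < 0L | ids >= npaths], collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(seq_len(npaths) - 1L, ids)
  paths <- extract_original_paths(index)[keep + 1L]
  md <- index$metadata
  if (!is.null(md)) md <- md[keep + 1L, , drop = FALSE]
  gbwt_build(paths, both_orientations = index$both,
             sample_interval = index$sample_interval, metadata = md)
}
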