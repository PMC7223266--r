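# The GBWT proper: per-node records with run-length encoded bodies,
# positional rank/LF, find/locate/extract, bidirectional search and a
# portable serialization. The heavy lifting is done in compiled code; this
# file holds the user-facing surface and the index container.

GBWT_MAGIC <- charToRaw("GBWTR")
GBWT_FORMAT_VERSION <- 1L
GBWT_ORIENTATION_ENCODING <- 1L  # 2n / 2n+1, 0 = end-marker

empty_core <- function() {
  list(nodes = integer(0), hdr_ptr = 0L, hdr_succ = integer(0),
       hdr_rank = integer(0), run_ptr = 0L, run_succ = integer(0),
       run_len = integer(0), blen = integer(0), smp_node = integer(0),
       smp_off = integer(0), smp_id = integer(0), n_paths = 0L)
}

new_gbwt <- function(core, sample_interval, both, metadata) {
  x <- list(core = core, sample_interval = as.integer(sample_interval),
            both = isTRUE(both), metadata = metadata)
  class(x) <- "gbwt"
  x
}

#' @method print gbwt
#' @export
print.gbwt <- function(x, ...) {
  s <- gbwt_stats(x)
  cat(sprintf(
    "GBWT index: %d sequence(s)%s, %d node record(s), %d run(s), total length %d\n",
    s$sequences, if (x$both) " (both orientations)" else "", s$nodes, s$runs,
    s$length))
  cat(sprintf("sample interval d = %d (%d sampled position(s))\n",
              x$sample_interval, s$samples))
  invisible(x)
}

#' Index summary statistics
#'
#' @param index A `gbwt` index.
#' @return A list with `sequences`, `paths` (original paths, i.e. sequences
#'   halved when both orientations are indexed), `nodes` (non-empty records,
#'   excluding the end-marker record), `runs`, `length` (total body length)
#'   and `samples`.
#' @export
gbwt_stats <- function(index) {
  co <- index$core
  nseq <- co$n_paths
  list(sequences = nseq,
       paths = if (index$both) nseq %/% 2L else nseq,
       nodes = sum(co$nodes != 0L),
       runs = length(co$run_succ),
       length = sum(co$blen),
       samples = length(co$smp_id))
}

#' Number of indexed sequences
#' @param index A `gbwt` index.
#' @export
gbwt_n_sequences <- function(index) index$core$n_paths

validate_paths <- function(paths) {
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (length(p) == 0L) {
      stop("empty path in batch at position ", i, call. = FALSE)
    }
    if (any(is.na(p)) || any(p <= 0L)) {
      stop("path ", i, " contains an invalid node value (must be > 0)",
           call. = FALSE)
    }
  }
  lapply(paths, as.integer)
}

with_orientations <- function(paths, both) {
  if (!both) return(paths)
  out <- vector("list", 2L * length(paths))
  for (j in seq_along(paths)) {
    out[[2L * j - 1L]] <- paths[[j]]
    out[[2L * j]] <- reverse_path(paths[[j]])
  }
  out
}

#' Build a GBWT index over a collection of paths
#'
#' When `both_orientations = TRUE` (the default, giving an FMD-style index
#' that supports bidirectional search), sequence `2j` is path `j` and
#' sequence `2j + 1` is its reverse path.
#'
#' @param paths List of integer vectors of oriented node values (each
#'   non-empty, all values > 0).
#' @param both_orientations Index the reverse path of every path as well.
#' @param sample_interval Path-identifier sampling interval `d`: every
#'   on-path offset divisible by `d`, plus every final position, stores its
#'   path identifier for `locate()`.
#' @param metadata Optional data.frame with one row per path and columns
#'   `sample`, `phase`, `contig`, `fragment` (unique rows).
#' @return A `gbwt` index.
#' @export
gbwt_build <- function(paths, both_orientations = TRUE,
                       sample_interval = 1024L, metadata = NULL) {
  paths <- validate_paths(paths)
  check_metadata(metadata, length(paths))
  seqs <- with_orientations(paths, both_orientations)
  core <- gbwt_insert_cpp(empty_core(), seqs, as.integer(sample_interval))
  new_gbwt(core, sample_interval, both_orientations, metadata)
}

check_metadata <- function(metadata, n) {
  if (is.null(metadata)) return(invisible(NULL))
  need <- c("sample", "phase", "contig", "fragment")
  if (!all(need %in% names(metadata))) {
    stop("metadata needs columns sample, phase, contig, fragment", call. = FALSE)
  }
  if (nrow(metadata) != n) {
    stop("metadata must have one row per path", call. = FALSE)
  }
  key <- do.call(paste, metadata[need])
  if (anyDuplicated(key)) stop("metadata rows must be unique", call. = FALSE)
  invisible(NULL)
}

#' Insert a batch of paths into an existing index
#'
#' New paths get consecutive identifiers in batch order; the result is
#' structurally identical to a fresh build over the previous paths plus the
#' batch. With both orientations, each path contributes its reverse as well.
#'
#' @param index A `gbwt` index.
#' @param paths List of paths (may be empty, returning the index unchanged).
#' @param metadata Optional metadata rows for the new paths.
#' @return The updated `gbwt` index.
#' @export
gbwt_insert <- function(index, paths, metadata = NULL) {
  if (length(paths) == 0L) return(index)
  paths <- validate_paths(paths)
  check_metadata(metadata, length(paths))
  seqs <- with_orientations(paths, index$both)
  core <- gbwt_insert_cpp(index$core, seqs, index$sample_interval)
  md <- index$metadata
  if (!is.null(metadata)) {
    md <- if (is.null(md)) metadata else rbind(md, metadata)
  }
  new_gbwt(core, index$sample_interval, index$both, md)
}

# ---- Records ---------------------------------------------------------------

#' Extract one node record
#'
#' @param index A `gbwt` index.
#' @param node Oriented node value (0 for the end-marker record).
#' @return `NULL` when the record is empty, else a list with `header`
#'   (data.frame `successor`, `rank`: the local alphabet with cumulative
#'   occurrence counts over all smaller records) and `runs` (data.frame
#'   `code`, `successor`, `length`: the run-length encoded body; `code` is
#'   the 0-based index into the local alphabet).
#' @export
gbwt_record <- function(index, node) {
  co <- index$core
  ri <- match(as.integer(node), co$nodes)
  if (is.na(ri)) return(NULL)
  hi <- (co$hdr_ptr[ri] + 1L):co$hdr_ptr[ri + 1L]
  ki <- (co$run_ptr[ri] + 1L):co$run_ptr[ri + 1L]
  header <- data.frame(successor = co$hdr_succ[hi], rank = co$hdr_rank[hi])
  runs <- data.frame(code = match(co$run_succ[ki], header$successor) - 1L,
                     successor = co$run_succ[ki], length = co$run_len[ki])
  list(header = header, runs = runs, body_length = co$blen[ri])
}

#' Rank of a successor within a record prefix
#'
#' Counts occurrences of successor `w` among the first `i` body symbols of a
#' record, by scanning runs. A successor absent from the header yields 0.
#'
#' @param record A record as returned by [gbwt_record()].
#' @param i Prefix length, `0 <= i <=` body length.
#' @param w Oriented node value (or 0 for the end-marker successor).
#' @return Integer count.
#' @export
record_rank <- function(record, i, w) {
  if (is.null(record) || i <= 0L) return(0L)
  if (i > record$body_length) stop("prefix length exceeds body length", call. = FALSE)
  len <- record$runs$length
  ends <- cumsum(len)
  starts <- ends - len
  take <- pmax(0L, pmin(len, i - starts))
  sum(take[record$runs$successor == w])
}

# ---- Positions and search states ------------------------------------------

gbwt_state <- function(node, sp, ep) {
  list(node = as.integer(node), sp = as.integer(sp), ep = as.integer(ep))
}

empty_state <- function() gbwt_state(-1L, 0L, -1L)

#' Size of a search state (number of matching occurrences)
#' @param state A search state from [gbwt_find()] or [gbwt_extend()].
#' @export
state_size <- function(state) {
  if (is.null(state) || state$ep < state$sp) return(0L)
  state$ep - state$sp + 1L
}

#' Positional LF-mapping
#'
#' Maps position (`node`, `offset`) to the position of the following
#' occurrence of successor `w`:
#' `LF((v, i), w) = (w, rank(v, w) + rank_in_body(v, i, w))`.
#'
#' @param index A `gbwt` index.
#' @param node,offset The position.
#' @param w Successor node value (> 0).
#' @return A list with `node`, `offset`, or `NULL` when `w` is absent from
#'   the record's header (search failure, not an error).
#' @export
gbwt_lf <- function(index, node, offset, w) {
  if (w <= 0L) stop("cannot LF-map on the end-marker", call. = FALSE)
  r <- gbwt_lf_cpp(index$core, as.integer(node), as.integer(offset),
                   as.integer(w))
  if (r[1] < 0L) return(NULL)
  list(node = r[1], offset = r[2])
}

#' Extend a search state by one node
#'
#' @param index A `gbwt` index.
#' @param state A search state.
#' @param w Oriented node value to append to the pattern.
#' @return The new state (possibly empty; empty in, empty out).
#' @export
gbwt_extend <- function(index, state, w) {
  if (state_size(state) == 0L) return(empty_state())
  r <- gbwt_extend_cpp(index$core, state$node, state$sp, state$ep,
                       as.integer(w))
  gbwt_state(r[1], r[2], r[3])
}

#' Find the occurrences of a pattern path
#'
#' Returns the search state whose range size equals the number of
#' occurrences of the pattern as a contiguous subpath over all indexed
#' sequences.
#'
#' @param index A `gbwt` index.
#' @param pattern Non-empty integer vector of oriented node values.
#' @return A search state (`node`, `sp`, `ep`); empty when absent.
#' @export
gbwt_find <- function(index, pattern) {
  if (length(pattern) == 0L) stop("empty pattern", call. = FALSE)
  r <- gbwt_find_cpp(index$core, as.integer(pattern))
  gbwt_state(r[1], r[2], r[3])
}

#' Locate the sequence identifiers of a search state
#'
#' Returns one identifier per occurrence in the range (a multiset;
#' de-duplication is left to the caller). The direct method iterates LF from
#' each position until a sampled position is reached and preserves range
#' order; the fast method advances whole ranges one run at a time and
#' returns the identifiers sorted.
#'
#' @param index A `gbwt` index.
#' @param state A search state.
#' @param method `"direct"` or `"fast"`.
#' @return Integer vector of sequence identifiers.
#' @export
gbwt_locate <- function(index, state, method = c("direct", "fast")) {
  method <- match.arg(method)
  if (state_size(state) == 0L) return(integer(0))
  if (method == "direct") {
    gbwt_locate_direct_cpp(index$core, state$node, state$sp, state$ep)
  } else {
    gbwt_locate_fast_cpp(index$core, state$node, state$sp, state$ep)
  }
}

#' Extract an indexed sequence
#'
#' Walks forward from the end-marker record at offset `j`, consuming LF
#' steps until the end-marker successor, and returns the exact node
#' sequence originally inserted.
#'
#' @param index A `gbwt` index.
#' @param j Sequence identifier, `0 <= j <` number of indexed sequences.
#' @return Integer vector of oriented node values.
#' @export
gbwt_extract <- function(index, j) {
  n <- gbwt_n_sequences(index)
  if (j < 0L || j >= n) {
    stop("sequence identifier out of range: ", j, call. = FALSE)
  }
  gbwt_extract_cpp(index$core, as.integer(j))
}

# ---- Bidirectional (FMD-style) search -------------------------------------

bd_state <- function(fwd, bwd, len) list(forward = fwd, backward = bwd,
                                         pattern_length = as.integer(len))

#' Start a bidirectional search on a single node
#'
#' Requires an index built with both orientations. The forward state tracks
#' the pattern, the backward state its reverse path; their ranges always
#' have equal size.
#'
#' @param index A `gbwt` index with `both = TRUE`.
#' @param v Oriented node value.
#' @return A bidirectional state.
#' @export
gbwt_bd_init <- function(index, v) {
  if (!index$both) {
    stop("bidirectional search needs an index with both orientations",
         call. = FALSE)
  }
  f <- gbwt_find(index, v)
  b <- gbwt_find(index, node_reverse(v))
  bd_state(f, b, 1L)
}

bd_empty <- function() bd_state(empty_state(), empty_state(), 0L)

#' Extend a bidirectional search state
#'
#' Forward extension appends `w` to the pattern; backward extension prepends
#' it. The co-range is updated by partitioning the extending record's range
#' by successor: occurrences followed by the end-marker come first, the rest
#' in the order of the reversed successors.
#'
#' @param index A `gbwt` index with both orientations.
#' @param bs A bidirectional state.
#' @param w Oriented node value.
#' @param direction `"forward"` (append) or `"backward"` (prepend).
#' @return The new bidirectional state (possibly empty).
#' @export
gbwt_bd_extend <- function(index, bs, w, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (!index$both) {
    stop("bidirectional search needs an index with both orientations",
         call. = FALSE)
  }
  if (state_size(bs$forward) == 0L) return(bd_empty())
  w <- as.integer(w)
  if (direction == "forward") {
    f2 <- gbwt_extend(index, bs$forward, w)
    if (state_size(f2) == 0L) return(bd_empty())
    k <- bd_smaller_count(index, bs$forward, node_reverse(w))
    b2 <- gbwt_state(bs$backward$node, bs$backward$sp + k,
                     bs$backward$sp + k + state_size(f2) - 1L)
    bd_state(f2, b2, bs$pattern_length + 1L)
  } else {
    b2 <- gbwt_extend(index, bs$backward, node_reverse(w))
    if (state_size(b2) == 0L) return(bd_empty())
    k <- bd_smaller_count(index, bs$backward, w)
    f2 <- gbwt_state(bs$forward$node, bs$forward$sp + k,
                     bs$forward$sp + k + state_size(b2) - 1L)
    bd_state(f2, b2, bs$pattern_length + 1L)
  }
}

# occurrences in the state's range whose successor c sorts before threshold
# under the reverse ordering: end-markers first, then by reverse(c)
bd_smaller_count <- function(index, state, threshold) {
  m <- gbwt_range_succ_counts_cpp(index$core, state$node, state$sp, state$ep)
  if (nrow(m) == 0L) return(0L)
  succ <- m[, 1L]
  keys <- ifelse(succ == 0L, -1L, bitwXor(succ, 1L))
  sum(m[keys < threshold, 2L])
}

# ---- Serialization ---------------------------------------------------------

core_fields <- c("nodes", "hdr_ptr", "hdr_succ", "hdr_rank", "run_ptr",
                 "run_succ", "run_len", "blen", "smp_node", "smp_off",
                 "smp_id")

#' Serialize a GBWT index
#'
#' Deterministic little-endian binary container: magic `GBWTR`, a format
#' version byte, header integers (orientation encoding, flags, sample
#' interval, sequence count), length-prefixed integer vectors for the
#' records and sample table, the metadata table, and a trailing checksum.
#'
#' @param index A `gbwt` index.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
gbwt_write <- function(index, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(GBWT_MAGIC, con)
  writeBin(as.raw(GBWT_FORMAT_VERSION), con)
  ck <- 0
  put <- function(x) {
    x <- as.integer(x)
    ck <<- (ck + sum(as.double(x) %% 2147483647)) %% 2147483647
    writeBin(x, con, size = 4L, endian = "little")
  }
  put(GBWT_ORIENTATION_ENCODING)
  put(as.integer(index$both))
  put(index$sample_interval)
  put(index$core$n_paths)
  for (f in core_fields) {
    v <- index$core[[f]]
    put(length(v))
    put(v)
  }
  md <- index$metadata
  if (is.null(md)) {
    put(-1L)
  } else {
    put(nrow(md))
    for (i in seq_len(nrow(md))) {
      for (col in c("sample", "contig")) {
        b <- utf8ToInt(as.character(md[[col]][i]))
        put(length(b))
        put(b)
      }
      put(md$phase[i])
      put(md$fragment[i])
    }
  }
  put(as.integer(ck %% 2147483647))
  invisible(file)
}

#' Deserialize a GBWT index
#'
#' Verifies magic, version and checksum; truncated or corrupted input raises
#' a malformed-index error.
#'
#' @param file Path to a file written by [gbwt_write()].
#' @return A `gbwt` index.
#' @export
gbwt_read <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = length(GBWT_MAGIC))
  if (length(magic) < length(GBWT_MAGIC) || !identical(magic, GBWT_MAGIC)) {
    stop("malformed index: bad magic", call. = FALSE)
  }
  ver <- readBin(con, "raw", n = 1L)
  if (length(ver) < 1L || as.integer(ver) != GBWT_FORMAT_VERSION) {
    stop("malformed index: unsupported format version", call. = FALSE)
  }
  ck <- 0
  get <- function(n) {
    x <- readBin(con, "integer", n = n, size = 4L, endian = "little")
    if (length(x) < n) stop("malformed index: truncated file", call. = FALSE)
    ck <<- (ck + sum(as.double(x) %% 2147483647)) %% 2147483647
    x
  }
  if (get(1L) != GBWT_ORIENTATION_ENCODING) {
    stop("malformed index: unknown orientation encoding", call. = FALSE)
  }
  both <- get(1L) == 1L
  d <- get(1L)
  n_paths <- get(1L)
  core <- list()
  for (f in core_fields) core[[f]] <- get(get(1L))
  core$n_paths <- n_paths
  nmd <- get(1L)
  md <- NULL
  if (nmd >= 0L) {
    rows <- vector("list", nmd)
    for (i in seq_len(nmd)) {
      sample <- intToUtf8(get(get(1L)))
      contig <- intToUtf8(get(get(1L)))
      phase <- get(1L)
      fragment <- get(1L)
      rows[[i]] <- data.frame(sample = sample, phase = phase, contig = contig,
                              fragment = fragment)
    }
    md <- if (nmd > 0L) do.call(rbind, rows) else
      data.frame(sample = character(0), phase = integer(0),
                 contig = character(0), fragment = integer(0))
  }
  want <- as.double(ck)
  stored <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(stored) < 1L) stop("malformed index: truncated file", call. = FALSE)
  if (as.double(stored) != want %% 2147483647) {
    stop("malformed index: checksum mismatch", call. = FALSE)
  }
  new_gbwt(core, d, both, md)
}

#' Structural equality of two GBWT indexes
#'
#' Compares records (headers and runs), the end-marker record, the sample
#' table, flags, sample interval and metadata.
#'
#' @param a,b Two `gbwt` indexes.
#' @return `TRUE` or `FALSE`.
#' @export
gbwt_identical <- function(a, b) {
  for (f in c(core_fields, "n_paths")) {
    if (!identical(as.integer(a$core[[f]]), as.integer(b$core[[f]]))) {
      return(FALSE)
    }
  }
  if (!identical(a$both, b$both)) return(FALSE)
  if (!identical(as.integer(a$sample_interval), as.integer(b$sample_interval))) {
    return(FALSE)
  }
  ma <- a$metadata
  mb <- b$metadata
  if (is.null(ma) != is.null(mb)) return(FALSE)
  if (!is.null(ma)) {
    rownames(ma) <- NULL
    rownames(mb) <- NULL
    if (!isTRUE(all.equal(ma, mb, check.attributes = FALSE))) return(FALSE)
  }
  TRUE
}
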