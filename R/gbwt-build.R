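# Batched construction: a node-capacity buffer in front of the incremental
# (BCR-style) inserter. Paths are flushed in insertion order; building in
# any batch partition yields a structurally identical index.

#' Create a construction buffer
#'
#' Pending paths accumulate until their total node count reaches the
#' capacity, at which point they are flushed into the index in insertion
#' order.
#'
#' @param index A `gbwt` index to insert into (default: a fresh empty index).
#' @param capacity Flush threshold in total buffered nodes. The default
#'   (100 million) suits large cohorts; tests use small values.
#' @return A construction buffer (environment with class `gbwt_buffer`).
#' @export
gbwt_buffer <- function(index = gbwt_build(list()), capacity = 1e8) {
  buf <- new.env(parent = emptyenv())
  buf$index <- index
  buf$capacity <- capacity
  buf$pending <- list()
  buf$pending_meta <- list()
  buf$nodes <- 0L
  class(buf) <- "gbwt_buffer"
  buf
}

#' Add a path to a construction buffer
#'
#' Triggers a flush when the node capacity is reached.
#'
#' @param buf A `gbwt_buffer`.
#' @param path Integer vector of oriented node values.
#' @param metadata Optional single metadata row for the path.
#' @return The buffer, invisibly.
#' @export
buffer_add <- function(buf, path, metadata = NULL) {
  buf$pending[[length(buf$pending) + 1L]] <- path
  buf$pending_meta[[length(buf$pending)]] <- metadata
  buf$nodes <- buf$nodes + length(path)
  if (buf$nodes >= buf$capacity) buffer_flush(buf)
  invisible(buf)
}

#' Flush a construction buffer
#'
#' @param buf A `gbwt_buffer`.
#' @return The buffer, invisibly; the updated index is in `buf$index`.
#' @export
buffer_flush <- function(buf) {
  if (length(buf$pending)) {
    md <- NULL
    if (any(!vapply(buf$pending_meta, is.null, logical(1)))) {
      md <- do.call(rbind, buf$pending_meta)
    }
    buf$index <- gbwt_insert(buf$index, buf$pending, md)
    buf$pending <- list()
    buf$pending_meta <- list()
    buf$nodes <- 0L
  }
  invisible(buf)
}

#' @method print gbwt_buffer
#' @export
print.gbwt_buffer <- function(x, ...) {
  cat(sprintf("GBWT construction buffer: %d pending path(s), %d/%g nodes\n",
              length(x$pending), x$nodes, x$capacity))
  invisible(x)
}
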