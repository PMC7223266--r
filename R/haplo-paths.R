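# From a reference FASTA and a phased VCF to haplotype paths: build the
# variation graph (reference backbone split at variant boundaries and at a
# maximum node length, alternate alleles as node chains, deletions as
# edges), then thread each phased sample through the allele paths, with
# overlap resolution and phase breaks. A plain-text staging bundle lets the
# parsed information be reused without re-reading the VCF.

#' Build a variation graph from a reference and variants
#'
#' The reference of each contig is split into backbone nodes at every
#' variant boundary and at `max_node_len`; each alternate allele becomes a
#' chain of new nodes (a deletion becomes an edge bypassing the deleted
#' backbone nodes). Records with symbolic or breakend alleles are skipped
#' and counted. Shared leading bases of REF/ALT (the VCF anchor base) are
#' stripped before the site interval is computed.
#'
#' @param reference Path to a FASTA file, or a named character vector of
#'   contig sequences.
#' @param variants Path to a VCF file, a `vcfR` object, or `NULL` for no
#'   variants.
#' @param max_node_len Maximum node label length in bases (default 32).
#' @return A `vg_build` object: `graph` (a `bdgraph` whose reference paths
#'   cover each contig), `sites` (per variant record: `contig`, `start`,
#'   `end` 0-based half-open, `alleles` node paths with index 1 = reference
#'   allele, `allele_seqs`), `contigs` (backbone layout) and `skipped`
#'   (count of unsupported records).
#' @export
construct_graph <- function(reference, variants = NULL, max_node_len = 32L) {
  ref <- read_reference(reference)
  var <- read_variant_table(variants)
  if (!is.null(var) && nrow(var) && !all(var$contig %in% names(ref))) {
    stop("VCF contig absent from the reference: ",
         paste(setdiff(unique(var$contig), names(ref)), collapse = ", "),
         call. = FALSE)
  }
  labels <- character(0)
  edges <- matrix(integer(0), ncol = 2L)
  next_id <- 1L
  new_node <- function(lab) {
    id <- next_id
    next_id <<- next_id + 1L
    labels[as.character(id)] <<- lab
    id
  }
  contigs <- list()
  sites <- list()
  skipped <- 0L
  for (ct in names(ref)) {
    seq <- ref[[ct]]
    L <- nchar(seq)
    v <- if (is.null(var)) NULL else var[var$contig == ct, , drop = FALSE]
    recs <- list()
    if (!is.null(v) && nrow(v)) {
      for (i in seq_len(nrow(v))) {
        alts <- strsplit(v$alt[i], ",", fixed = TRUE)[[1]]
        if (any(is_symbolic_allele(alts))) {
          skipped <- skipped + 1L
          warning("skipping symbolic/breakend record at ", ct, ":", v$pos[i],
                  call. = FALSE)
          next
        }
        rs <- v$ref[i]
        lcp <- 0L
        repeat {
          if (lcp >= nchar(rs)) break
          ch <- substr(rs, lcp + 1L, lcp + 1L)
          if (all(nchar(alts) > lcp) &&
              all(substr(alts, lcp + 1L, lcp + 1L) == ch)) lcp <- lcp + 1L
          else break
        }
        s <- v$pos[i] - 1L + lcp             # 0-based start
        e <- s + nchar(rs) - lcp             # half-open end
        if (e > L) stop("variant overruns contig ", ct, call. = FALSE)
        if (substr(seq, s + 1L, e) != substr(rs, lcp + 1L, nchar(rs))) {
          stop("REF mismatch with the reference at ", ct, ":", v$pos[i],
               call. = FALSE)
        }
        recs[[length(recs) + 1L]] <-
          list(start = s, end = e,
               alt_seqs = substring(alts, lcp + 1L))
      }
    }
    ord <- order(vapply(recs, `[[`, integer(1), "start"))
    recs <- recs[ord]
    cuts <- sort(unique(c(0L, L,
                          unlist(lapply(recs, function(r) c(r$start, r$end))))))
    bounds <- integer(0)
    for (k in seq_len(length(cuts) - 1L)) {
      a <- cuts[k]
      b <- cuts[k + 1L]
      bounds <- c(bounds, seq(a, b - 1L, by = max_node_len))
    }
    bounds <- sort(unique(c(bounds, L)))
    nb <- length(bounds) - 1L
    ref_ids <- integer(nb)
    for (k in seq_len(nb)) {
      ref_ids[k] <- new_node(substr(seq, bounds[k] + 1L, bounds[k + 1L]))
    }
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L]
    if (nb > 1L) {
      edges <- rbind(edges, cbind(node_encode(ref_ids[-nb]),
                                  node_encode(ref_ids[-1L])))
    }
    node_before <- function(pos) {        # backbone node ending at pos
      k <- match(pos, ends)
      if (is.na(k)) NA_integer_ else ref_ids[k]
    }
    node_after <- function(pos) {         # backbone node starting at pos
      k <- match(pos, starts)
      if (is.na(k)) NA_integer_ else ref_ids[k]
    }
    for (r in recs) {
      ref_path <- node_encode_maybe(ref_ids[starts >= r$start & ends <= r$end])
      alleles <- list(ref_path)
      allele_seqs <- substr(seq, r$start + 1L, r$end)
      for (aseq in r$alt_seqs) {
        if (nchar(aseq) == 0L) {
          alleles[[length(alleles) + 1L]] <- integer(0)
          allele_seqs <- c(allele_seqs, "")
          u <- node_before(r$start)
          w <- node_after(r$end)
          if (!is.na(u) && !is.na(w)) {
            edges <- rbind(edges, c(node_encode(u), node_encode(w)))
          }
          next
        }
        pieces <- substring(aseq,
                            seq(1L, nchar(aseq), by = max_node_len),
                            pmin(seq(max_node_len, nchar(aseq) + max_node_len - 1L,
                                     by = max_node_len), nchar(aseq)))
        chain <- vapply(pieces, new_node, integer(1), USE.NAMES = FALSE)
        if (length(chain) > 1L) {
          edges <- rbind(edges, cbind(node_encode(chain[-length(chain)]),
                                      node_encode(chain[-1L])))
        }
        u <- node_before(r$start)
        w <- node_after(r$end)
        if (!is.na(u)) edges <- rbind(edges, c(node_encode(u), node_encode(chain[1L])))
        if (!is.na(w)) edges <- rbind(edges, c(node_encode(chain[length(chain)]),
                                               node_encode(w)))
        alleles[[length(alleles) + 1L]] <- node_encode(chain)
        allele_seqs <- c(allele_seqs, aseq)
      }
      sites[[length(sites) + 1L]] <- list(contig = ct, start = r$start,
                                          end = r$end, alleles = alleles,
                                          allele_seqs = allele_seqs)
    }
    contigs[[ct]] <- list(length = L, ref_ids = ref_ids, starts = starts,
                          ends = ends, sequence = seq)
  }
  ref_paths <- lapply(contigs, function(ci) node_encode(ci$ref_ids))
  graph <- bd_graph(labels, edges, reference_paths = ref_paths)
  out <- list(graph = graph, sites = sites, contigs = contigs,
              skipped = skipped)
  class(out) <- "vg_build"
  out
}

# symbolic (<DEL>, <INS:ME>, ...), breakend ([ / ] notation) or overlap (*)
is_symbolic_allele <- function(a) {
  grepl("[<>]", a) | grepl("[", a, fixed = TRUE) |
    grepl("]", a, fixed = TRUE) | a == "*"
}

node_encode_maybe <- function(ids) {
  if (length(ids) == 0L) integer(0) else node_encode(ids)
}

#' @method print vg_build
#' @export
print.vg_build <- function(x, ...) {
  cat(sprintf("variation graph build: %d contig(s), %d node(s), %d site(s), %d record(s) skipped\n",
              length(x$contigs), length(x$graph$labels), length(x$sites),
              x$skipped))
  invisible(x)
}

read_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    ss <- Biostrings::readDNAStringSet(reference)
    ref <- as.character(ss)
    names(ref) <- sub("\\s.*$", "", names(ref))
    return(ref)
  }
  if (is.character(reference) && !is.null(names(reference))) {
    return(reference)
  }
  stop("reference must be a FASTA path or a named character vector",
       call. = FALSE)
}

read_variant_table <- function(variants) {
  if (is.null(variants)) return(NULL)
  if (inherits(variants, "vcfR")) {
    fix <- variants@fix
  } else if (is.character(variants) && length(variants) == 1L) {
    fix <- vcfR::read.vcfR(variants, verbose = FALSE)@fix
  } else {
    stop("variants must be a VCF path, a vcfR object or NULL", call. = FALSE)
  }
  data.frame(contig = as.character(fix[, "CHROM"]),
             pos = as.integer(fix[, "POS"]),
             ref = as.character(fix[, "REF"]),
             alt = as.character(fix[, "ALT"]))
}

#' Parse phased genotypes into per-sample phasing rows
#'
#' Expects a diploid genome where some sites may be haploid. The GT field is
#' read per site: `a|b` phased diploid, `a/b` unphased diploid, `a`
#' haploid; missing genotypes (`.`) are treated as reference.
#'
#' @param variants VCF path or `vcfR` object.
#' @param build The matching `vg_build` (used to align records with sites).
#' @return A list of phasing rows: `sample`, `alleles` (sites x 2 integer
#'   matrix, NA = absent haplotype), `phased` (logical per site).
#' @export
read_phasing <- function(variants, build) {
  vcf <- if (inherits(variants, "vcfR")) variants else
    vcfR::read.vcfR(variants, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2L) return(list())
  keep <- vapply(strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE),
                 function(a) !any(is_symbolic_allele(a)), logical(1))
  gt <- gt[keep, , drop = FALSE]
  if (sum(keep) != length(build$sites)) {
    stop("variant records do not match the graph build", call. = FALSE)
  }
  samples <- colnames(gt)[-1L]
  lapply(samples, function(sm) {
    g <- sub(":.*$", "", gt[, sm])
    parts <- strsplit(g, "[|/]")
    a <- t(vapply(parts, function(p) {
      p[p == "."] <- "0"
      if (length(p) == 1L) c(as.integer(p), NA_integer_)
      else as.integer(p[1:2])
    }, integer(2)))
    list(sample = sm, alleles = a, phased = grepl("|", g, fixed = TRUE) |
           !grepl("/", g, fixed = TRUE))
  })
}

#' Thread one phased sample into haplotype paths
#'
#' For each haplotype, reference backbone nodes are appended until the next
#' chosen alternate site, then the allele's node path. When a site's
#' reference interval overlaps the already generated path, the overlap is
#' resolved by (1) skipping allele-path nodes already emitted, then (2)
#' truncating emitted trailing reference nodes back to the site start; if
#' neither applies, the `phase-break` policy closes the fragment and starts
#' a new one with the allele path, while `force-ref` replaces the alternate
#' with the reference allele. An unphased heterozygous site is treated as a
#' phase break under `phase-break` and as reference under `force-ref`.
#'
#' @param build A `vg_build`.
#' @param row A phasing row (see [read_phasing()]).
#' @param policy `"phase-break"` or `"force-ref"`.
#' @return A list with `paths` (fragments as oriented node vectors) and
#'   `metadata` (one row per fragment: `sample`, `phase`, `contig`,
#'   `fragment`).
#' @export
generate_haplotype_paths <- function(build, row,
                                     policy = c("phase-break", "force-ref")) {
  policy <- match.arg(policy)
  n_sites <- length(build$sites)
  if (nrow(row$alleles) != n_sites) {
    stop("phasing row does not cover all sites", call. = FALSE)
  }
  paths <- list()
  meta <- list()
  for (ct in names(build$contigs)) {
    ci <- build$contigs[[ct]]
    idx <- which(vapply(build$sites, `[[`, character(1), "contig") == ct)
    for (hap in 1:2) {
      al <- row$alleles[idx, hap]
      if (all(is.na(al)) && length(idx)) next  # haplotype absent on contig
      frag <- 0L
      cur <- integer(0)        # emitted oriented nodes
      is_ref <- logical(0)     # parallel: backbone node?
      ref_start <- integer(0)  # parallel: backbone start (NA for alt nodes)
      cur_pos <- 0L
      close_frag <- function() {
        if (length(cur)) {
          paths[[length(paths) + 1L]] <<- cur
          meta[[length(meta) + 1L]] <<- data.frame(
            sample = row$sample, phase = hap, contig = ct, fragment = frag)
          frag <<- frag + 1L
        }
        cur <<- integer(0)
        is_ref <<- logical(0)
        ref_start <<- integer(0)
      }
      emit_ref_until <- function(to) {
        sel <- ci$starts >= cur_pos & ci$ends <= to
        if (any(sel)) {
          cur <<- c(cur, node_encode(ci$ref_ids[sel]))
          is_ref <<- c(is_ref, rep(TRUE, sum(sel)))
          ref_start <<- c(ref_start, ci$starts[sel])
        }
        cur_pos <<- to
      }
      emit_alt <- function(apath, e) {
        if (length(apath)) {
          cur <<- c(cur, apath)
          is_ref <<- c(is_ref, rep(FALSE, length(apath)))
          ref_start <<- c(ref_start, rep(NA_integer_, length(apath)))
        }
        cur_pos <<- e
      }
      for (k in seq_along(idx)) {
        site <- build$sites[[idx[k]]]
        a <- al[k]
        if (is.na(a)) a <- 0L
        unphased_het <- !row$phased[idx[k]] &&
          !is.na(row$alleles[idx[k], 1L]) &&
          !is.na(row$alleles[idx[k], 2L]) &&
          row$alleles[idx[k], 1L] != row$alleles[idx[k], 2L]
        if (unphased_het) {
          if (policy == "force-ref") {
            a <- 0L
          } else {  # phase break at the ambiguous site, on both haplotypes
            if (cur_pos <= site$start) emit_ref_until(site$start)
            close_frag()
          }
        }
        if (a == 0L) next
        if (a + 1L > length(site$alleles)) {
          stop("allele index ", a, " out of range at site ", site$contig, ":",
               site$start + 1L, call. = FALSE)
        }
        apath <- site$alleles[[a + 1L]]
        if (cur_pos <= site$start) {
          emit_ref_until(site$start)
          emit_alt(apath, site$end)
          next
        }
        # overlap: try truncating emitted trailing reference nodes to start
        drop <- 0L
        while (drop < length(cur) &&
               is_ref[length(cur) - drop] &&
               ref_start[length(cur) - drop] >= site$start) drop <- drop + 1L
        trunc_to <- if (drop > 0L) ref_start[length(cur) - drop + 1L] else NA
        if (!is.na(trunc_to) && trunc_to == site$start) {
          kp <- seq_len(length(cur) - drop)
          cur <- cur[kp]
          is_ref <- is_ref[kp]
          ref_start <- ref_start[kp]
          cur_pos <- site$start
          emit_alt(apath, site$end)
        } else if (policy == "force-ref") {
          # unresolvable: keep the reference allele, which continues naturally
        } else {
          close_frag()
          emit_alt(apath, site$end)
        }
      }
      emit_ref_until(ci$length)
      close_frag()
    }
  }
  md <- if (length(meta)) do.call(rbind, meta) else
    data.frame(sample = character(0), phase = integer(0),
               contig = character(0), fragment = integer(0))
  list(paths = paths, metadata = md)
}

#' Expected haplotype sequence by direct string substitution
#'
#' Applies the chosen allele sequences to the reference string using only
#' site coordinates (no graph), with the same overlap policy as
#' [generate_haplotype_paths()]; used as an independent check that
#' concatenated node labels spell the intended haplotype.
#'
#' @param build A `vg_build`.
#' @param contig Contig name.
#' @param alleles Integer vector of allele indices (0 = reference) for the
#'   contig's sites in order; NA = reference.
#' @param policy `"phase-break"` or `"force-ref"`.
#' @return Character vector of fragment sequences.
#' @export
haplotype_sequence <- function(build, contig, alleles,
                               policy = c("phase-break", "force-ref")) {
  policy <- match.arg(policy)
  ci <- build$contigs[[contig]]
  idx <- which(vapply(build$sites, `[[`, character(1), "contig") == contig)
  stopifnot(length(alleles) == length(idx))
  frags <- character(0)
  out <- ""
  cur_pos <- 0L
  last_alt_end <- 0L
  for (k in seq_along(idx)) {
    site <- build$sites[[idx[k]]]
    a <- alleles[k]
    if (is.na(a) || a == 0L) next
    aseq <- site$allele_seqs[a + 1L]
    if (cur_pos <= site$start) {
      out <- paste0(out, substr(ci$sequence, cur_pos + 1L, site$start))
      out <- paste0(out, aseq)
      cur_pos <- site$end
      last_alt_end <- site$end
    } else if (site$start >= last_alt_end) {
      # overlapped bases are plain reference: trim them off
      out <- substr(out, 1L, nchar(out) - (cur_pos - site$start))
      out <- paste0(out, aseq)
      cur_pos <- site$end
      last_alt_end <- site$end
    } else if (policy == "force-ref") {
      # keep reference; nothing to do
    } else {
      if (nchar(out)) frags <- c(frags, out)
      out <- aseq
      cur_pos <- site$end
      last_alt_end <- site$end
    }
  }
  out <- paste0(out, substr(ci$sequence, cur_pos + 1L, ci$length))
  if (nchar(out)) frags <- c(frags, out)
  frags
}

# ---- Staging bundle --------------------------------------------------------

rle_pack <- function(x) {
  x <- ifelse(is.na(x), ".", as.character(x))
  r <- rle(x)
  paste(paste0(r$values, "x", r$lengths), collapse = ",")
}

rle_unpack <- function(s) {
  if (!nzchar(s)) return(integer(0))
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "x", fixed = TRUE)
  unlist(lapply(parts, function(p) {
    v <- if (p[1] == ".") NA_integer_ else as.integer(p[1])
    rep(v, as.integer(p[2]))
  }))
}

#' Build a staging bundle from a graph build and phasing rows
#'
#' The bundle holds a main part (reference paths plus per-site allele
#' paths) and per-batch phasing parts (run-length encoded allele choices
#' for batches of `batch_size` samples), so that haplotype paths can be
#' generated without re-reading the VCF.
#'
#' @param build A `vg_build`.
#' @param rows Phasing rows from [read_phasing()].
#' @param batch_size Samples per phasing batch (default 200).
#' @return A `staging_bundle`.
#' @export
staging_bundle <- function(build, rows, batch_size = 200L) {
  n <- length(rows)
  nb <- if (n == 0L) 0L else ceiling(n / batch_size)
  batches <- lapply(seq_len(nb), function(b) {
    lo <- (b - 1L) * batch_size + 1L
    rows[lo:min(n, b * batch_size)]
  })
  out <- list(build = build, batches = batches,
              batch_size = as.integer(batch_size))
  class(out) <- "staging_bundle"
  out
}

#' Write a staging bundle to a directory
#'
#' Plain-text layout: `manifest.json`, `main.tsv` (reference paths, site
#' table, allele paths) and one `phasing_<b>.tsv` per batch (run-length
#' encoded allele choices). Batch files are independent: any subset can be
#' read back.
#'
#' @param bundle A `staging_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_staging <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  build <- bundle$build
  manifest <- list(format = "graphbwt-staging", version = 1L,
                   batch_size = bundle$batch_size,
                   n_batches = length(bundle$batches),
                   n_sites = length(build$sites),
                   contigs = names(build$contigs))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  main <- character(0)
  for (ct in names(build$contigs)) {
    ci <- build$contigs[[ct]]
    main <- c(main, paste("R", ct, ci$length,
                          paste(ci$ref_ids, collapse = ","),
                          paste(ci$starts, collapse = ","),
                          paste(ci$ends, collapse = ","),
                          ci$sequence, sep = "\t"))
  }
  for (k in seq_along(build$sites)) {
    s <- build$sites[[k]]
    main <- c(main, paste("V", k, s$contig, s$start, s$end,
                          length(s$alleles), sep = "\t"))
    for (a in seq_along(s$alleles)) {
      p <- s$alleles[[a]]
      main <- c(main, paste("A", k, a - 1L,
                            if (length(p)) paste(p, collapse = ",") else "-",
                            s$allele_seqs[a], sep = "\t"))
    }
  }
  # node labels and edges so the graph can be rebuilt from staging alone
  main <- c(main, paste("N", names(build$graph$labels),
                        unname(build$graph$labels), sep = "\t"))
  if (nrow(build$graph$edges)) {
    main <- c(main, paste("E", build$graph$edges[, 1L],
                          build$graph$edges[, 2L], sep = "\t"))
  }
  writeLines(main, file.path(dir, "main.tsv"))
  for (b in seq_along(bundle$batches)) {
    lines <- unlist(lapply(bundle$batches[[b]], function(row) {
      paste("G", row$sample,
            rle_pack(row$alleles[, 1L]),
            rle_pack(row$alleles[, 2L]),
            rle_pack(as.integer(row$phased)), sep = "\t")
    }))
    writeLines(lines, file.path(dir, sprintf("phasing_%d.tsv", b)))
  }
  invisible(dir)
}

#' Read a staging bundle from a directory
#'
#' @param dir Directory written by [write_staging()].
#' @param batches Integer vector of batch numbers to read (default: all).
#'   A missing batch file is an error listing the gap.
#' @return A `staging_bundle` (with only the requested batches).
#' @export
read_staging <- function(dir, batches = NULL) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "graphbwt-staging")) {
    stop("not a staging directory: ", dir, call. = FALSE)
  }
  if (is.null(batches)) batches <- seq_len(manifest$n_batches)
  missing <- batches[!file.exists(file.path(dir, sprintf("phasing_%d.tsv", batches)))]
  if (length(missing)) {
    stop("missing staging batch file(s): ",
         paste(sprintf("phasing_%d.tsv", missing), collapse = ", "),
         call. = FALSE)
  }
  main <- readLines(file.path(dir, "main.tsv"))
  f <- strsplit(main, "\t", fixed = TRUE)
  tag <- vapply(f, `[[`, character(1), 1L)
  contigs <- list()
  labels <- character(0)
  edges <- matrix(integer(0), ncol = 2L)
  sites <- list()
  for (x in f[tag == "R"]) {
    contigs[[x[2]]] <- list(length = as.integer(x[3]),
                            ref_ids = as.integer(strsplit(x[4], ",")[[1]]),
                            starts = as.integer(strsplit(x[5], ",")[[1]]),
                            ends = as.integer(strsplit(x[6], ",")[[1]]),
                            sequence = x[7])
  }
  for (x in f[tag == "V"]) {
    sites[[as.integer(x[2])]] <- list(contig = x[3], start = as.integer(x[4]),
                                      end = as.integer(x[5]), alleles = list(),
                                      allele_seqs = character(0))
  }
  for (x in f[tag == "A"]) {
    k <- as.integer(x[2])
    p <- if (x[4] == "-") integer(0) else as.integer(strsplit(x[4], ",")[[1]])
    sites[[k]]$alleles[[as.integer(x[3]) + 1L]] <- p
    sites[[k]]$allele_seqs <- c(sites[[k]]$allele_seqs,
                                if (length(x) >= 5L) x[5] else "")
  }
  for (x in f[tag == "N"]) labels[x[2]] <- x[3]
  em <- f[tag == "E"]
  if (length(em)) {
    edges <- cbind(as.integer(vapply(em, `[[`, character(1), 2L)),
                   as.integer(vapply(em, `[[`, character(1), 3L)))
  }
  ref_paths <- lapply(contigs, function(ci) node_encode(ci$ref_ids))
  build <- list(graph = bd_graph(labels, edges, reference_paths = ref_paths),
                sites = sites, contigs = contigs, skipped = 0L)
  class(build) <- "vg_build"
  rows <- list()
  for (b in sort(batches)) {
    lines <- readLines(file.path(dir, sprintf("phasing_%d.tsv", b)))
    for (ln in lines) {
      x <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- list(
        sample = x[2],
        alleles = cbind(rle_unpack(x[3]), rle_unpack(x[4])),
        phased = rle_unpack(x[5]) == 1L)
    }
  }
  bundle <- staging_bundle(build, rows, manifest$batch_size)
  bundle
}

#' Index haplotypes from a reference and a phased VCF, end to end
#'
#' Builds the variation graph, threads every sample's haplotypes and
#' constructs the GBWT with structured path metadata, buffering insertions.
#'
#' @param reference FASTA path or named character vector.
#' @param variants VCF path or `vcfR` object.
#' @param policy Overlap policy (see [generate_haplotype_paths()]).
#' @param max_node_len Maximum node label length.
#' @param both_orientations,sample_interval Passed to [gbwt_build()].
#' @param buffer_size Construction buffer capacity in nodes.
#' @return A list with `index` (the `gbwt`) and `build` (the `vg_build`).
#' @export
gbwt_index_vcf <- function(reference, variants,
                           policy = c("phase-break", "force-ref"),
                           max_node_len = 32L, both_orientations = TRUE,
                           sample_interval = 1024L, buffer_size = 1e8) {
  policy <- match.arg(policy)
  vcf <- if (inherits(variants, "vcfR")) variants else
    vcfR::read.vcfR(variants, verbose = FALSE)
  build <- construct_graph(reference, vcf, max_node_len)
  rows <- read_phasing(vcf, build)
  buf <- gbwt_buffer(gbwt_build(list(), both_orientations = both_orientations,
                                sample_interval = sample_interval),
                     capacity = buffer_size)
  for (row in rows) {
    hp <- generate_haplotype_paths(build, row, policy)
    for (i in seq_along(hp$paths)) {
      buffer_add(buf, hp$paths[[i]], hp$metadata[i, , drop = FALSE])
    }
  }
  buffer_flush(buf)
  list(index = buf$index, build = build)
}
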