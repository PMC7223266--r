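vcf_text <- function(body, samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body)
}

write_vcf <- function(lines) {
  tf <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(lines, tf)
  tf
}

test_that("a single SNV produces a bubble with two allele paths", {
  ref <- c(chr = "ACGTACGT")
  tf <- write_vcf(vcf_text("chr\t4\t.\tT\tG\t.\t.\t.\tGT\t0|1\t0|0"))
  b <- construct_graph(ref, tf, max_node_len = 32L)
  expect_identical(length(b$sites), 1L)
  s <- b$sites[[1]]
  expect_identical(c(s$start, s$end), c(3L, 4L))
  expect_identical(length(s$alleles), 2L)
  expect_identical(path_sequence(b$graph, s$alleles[[1]]), "T")
  expect_identical(path_sequence(b$graph, s$alleles[[2]]), "G")
  # reference path spells the reference
  expect_identical(path_sequence(b$graph, b$graph$reference_paths$chr),
                   "ACGTACGT")
  # both alleles are valid graph paths in context
  rows <- read_phasing(tf, b)
  hp <- generate_haplotype_paths(b, rows[[1]])
  expect_identical(nrow(hp$metadata), 2L)
  expect_identical(path_sequence(b$graph, hp$paths[[1]]), "ACGTACGT")
  expect_identical(path_sequence(b$graph, hp$paths[[2]]), "ACGGACGT")
  for (p in hp$paths) expect_true(is_path(b$graph, p))
})

test_that("no variants yields a node chain bounded by max_node_len", {
  ref <- c(chr = paste(rep("ACGTA", 20), collapse = ""))  # 100 bp
  b <- construct_graph(ref, NULL, max_node_len = 7L)
  expect_true(all(nchar(b$graph$labels) <= 7L))
  expect_identical(path_sequence(b$graph, b$graph$reference_paths$chr),
                   unname(ref))
})

test_that("deletions become bypass edges and insertions new nodes", {
  ref <- c(chr = "AACCGGTTAACC")
  tf <- write_vcf(vcf_text(c(
    "chr\t2\t.\tACCG\tA\t.\t.\t.\tGT\t1|0\t0|0",     # deletion of CCG
    "chr\t8\t.\tT\tTTTT\t.\t.\t.\tGT\t0|1\t0|0")))   # insertion TTT
  b <- construct_graph(ref, tf, max_node_len = 32L)
  del <- b$sites[[1]]
  expect_identical(c(del$start, del$end), c(2L, 5L))
  expect_identical(del$alleles[[2]], integer(0))  # pure deletion: an edge
  expect_lt(length(del$alleles[[2]]), length(del$alleles[[1]]))
  ins <- b$sites[[2]]
  expect_identical(c(ins$start, ins$end), c(8L, 8L))
  expect_identical(path_sequence(b$graph, ins$alleles[[2]]), "TTT")
  rows <- read_phasing(tf, b)
  hp <- generate_haplotype_paths(b, rows[[1]])
  expect_identical(path_sequence(b$graph, hp$paths[[1]]), "AAGTTAACC")
  expect_identical(path_sequence(b$graph, hp$paths[[2]]), "AACCGGTTTTTAACC")
})

test_that("threaded fragments spell the allele-substituted haplotypes", {
  set.seed(42)
  ref <- c(c1 = paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""))
  body <- c(
    "c1\t10\t.\tG\tC\t.\t.\t.\tGT\t1|0\t1|1",
    "c1\t30\t.\tCA\tC\t.\t.\t.\tGT\t0|1\t1|0",
    "c1\t50\t.\tT\tTAG\t.\t.\t.\tGT\t1|1\t0|1",
    "c1\t90\t.\tA\tG,T\t.\t.\t.\tGT\t2|1\t0|2",
    "c1\t150\t.\tC\tA\t.\t.\t.\tGT\t0|0\t1|0")
  # fix the REF fields to match the sampled reference
  body <- vapply(body, function(ln) {
    fs <- strsplit(ln, "\t")[[1]]
    pos <- as.integer(fs[2])
    fs[4] <- substr(ref, pos, pos + nchar(fs[4]) - 1L)
    if (fs[2] == "30") fs[5] <- substr(ref, pos, pos)
    if (fs[2] == "50") fs[5] <- paste0(fs[4], "AG")
    paste(fs, collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  tf <- write_vcf(vcf_text(body))
  b <- construct_graph(ref, tf, max_node_len = 16L)
  rows <- read_phasing(tf, b)
  for (row in rows) {
    hp <- generate_haplotype_paths(b, row)
    expect_identical(nrow(hp$metadata), 2L)  # no overlaps: one per haplotype
    for (i in seq_len(nrow(hp$metadata))) {
      want <- haplotype_sequence(b, "c1", row$alleles[, hp$metadata$phase[i]])
      expect_identical(path_sequence(b$graph, hp$paths[[i]]),
                       want[hp$metadata$fragment[i] + 1L])
      expect_true(is_path(b$graph, hp$paths[[i]]))
    }
  }
})

test_that("all-reference genotypes reproduce the reference path", {
  ref <- c(chr = "ACGTACGTACGT")
  tf <- write_vcf(vcf_text("chr\t6\t.\tC\tA\t.\t.\t.\tGT\t0|0\t0|0"))
  b <- construct_graph(ref, tf)
  rows <- read_phasing(tf, b)
  hp <- generate_haplotype_paths(b, rows[[1]])
  for (p in hp$paths) expect_identical(p, b$graph$reference_paths$chr)
})

test_that("overlapping deletions phase-break or force-ref as configured", {
  ref <- c(chr = "TTTTAAAACCCCGGGGTTTT")
  body <- c("chr\t4\t.\tTAAAAC\tT\t.\t.\t.\tGT\t1|0\t0|0",   # deletes [4,9)
            "chr\t8\t.\tACCCC\tA\t.\t.\t.\tGT\t1|0\t1|0")    # deletes [8,12)
  tf <- write_vcf(vcf_text(body))
  b <- construct_graph(ref, tf)
  rows <- read_phasing(tf, b)
  pb <- generate_haplotype_paths(b, rows[[1]], "phase-break")
  # haplotype 1 carries both deletions: exactly one extra fragment
  expect_identical(sum(pb$metadata$phase == 1L), 2L)
  expect_identical(sum(pb$metadata$phase == 2L), 1L)
  fr <- generate_haplotype_paths(b, rows[[1]], "force-ref")
  expect_identical(nrow(fr$metadata), 2L)
  # force-ref keeps the first deletion, replaces the second with reference
  h1 <- fr$paths[[which(fr$metadata$phase == 1L)]]
  expect_identical(path_sequence(b$graph, h1), "TTTTCCCGGGGTTTT")
  expect_identical(path_sequence(b$graph, h1),
                   haplotype_sequence(b, "chr", c(1L, 1L), "force-ref"))
  # string oracle agrees fragment-by-fragment under phase-break
  want <- haplotype_sequence(b, "chr", c(1L, 1L), "phase-break")
  got <- vapply(pb$paths[pb$metadata$phase == 1L],
                function(p) path_sequence(b$graph, p), character(1))
  expect_identical(got, want)
})

test_that("unphased heterozygotes break phase or fall back to reference", {
  ref <- c(chr = "ACGTACGTACGT")
  tf <- write_vcf(vcf_text("chr\t6\t.\tC\tG\t.\t.\t.\tGT\t0/1\t0|1"))
  b <- construct_graph(ref, tf)
  rows <- read_phasing(tf, b)
  pb <- generate_haplotype_paths(b, rows[[1]], "phase-break")
  # the ambiguity affects both haplotypes: each splits at the site
  expect_identical(nrow(pb$metadata), 4L)
  expect_identical(paste(vapply(pb$paths, function(p)
    path_sequence(b$graph, p), character(1)), collapse = "|"),
    "ACGTA|CGTACGT|ACGTA|GGTACGT")
  fr <- generate_haplotype_paths(b, rows[[1]], "force-ref")
  expect_identical(nrow(fr$metadata), 2L)
  for (p in fr$paths) expect_identical(path_sequence(b$graph, p), unname(ref))
  # phased sample is unaffected
  pb2 <- generate_haplotype_paths(b, rows[[2]], "phase-break")
  expect_identical(nrow(pb2$metadata), 2L)
})

test_that("unsupported records are skipped and errors are informative", {
  ref <- c(chr = "ACGTACGTACGT")
  tf <- write_vcf(vcf_text(c("chr\t2\t.\tC\t<DEL>\t.\t.\t.\tGT\t0|1\t0|0",
                             "chr\t6\t.\tC\tG\t.\t.\t.\tGT\t1|0\t0|0")))
  expect_warning(b <- construct_graph(ref, tf), "symbolic")
  expect_identical(b$skipped, 1L)
  expect_identical(length(b$sites), 1L)
  tf2 <- write_vcf(vcf_text("chrX\t2\t.\tC\tG\t.\t.\t.\tGT\t0|1\t0|0"))
  expect_error(construct_graph(ref, tf2), "contig")
  # allele index out of range names the site
  tf3 <- write_vcf(vcf_text("chr\t6\t.\tC\tG\t.\t.\t.\tGT\t1|0\t0|0"))
  b2 <- construct_graph(ref, tf3)
  rows <- read_phasing(tf3, b2)
  rows[[1]]$alleles[1, 1] <- 7L
  expect_error(generate_haplotype_paths(b2, rows[[1]]), "site chr:6")
})

test_that("staging bundles round trip and rebuild the same index", {
  set.seed(7)
  ref <- c(c1 = paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""))
  body <- vapply(c(15L, 40L, 77L, 101L), function(pos) {
    base <- substr(ref, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), base)[1]
    gt <- c("0|1", "1|0", "1|1", "0|0")[(pos %% 4L) + 1L]
    sprintf("c1\t%d\t.\t%s\t%s\t.\t.\t.\tGT\t%s\t%s", pos, base, alt, gt,
            c("1|0", "0|1", "0|0", "1|1")[(pos %% 4L) + 1L])
  }, character(1))
  tf <- write_vcf(vcf_text(body))
  res <- gbwt_index_vcf(ref, tf, max_node_len = 10L)
  rows <- read_phasing(tf, res$build)
  bundle <- staging_bundle(res$build, rows, batch_size = 1L)
  dir <- withr::local_tempdir()
  write_staging(bundle, dir)
  b2 <- read_staging(dir)
  expect_identical(length(b2$batches), 2L)
  # batch files are independently readable
  only2 <- read_staging(dir, batches = 2L)
  expect_identical(only2$batches[[1]][[1]]$sample, "S2")
  expect_error(read_staging(dir, batches = 3L), "phasing_3")
  # rebuilding from staging reproduces the index
  buf <- gbwt_buffer()
  for (row in unlist(b2$batches, recursive = FALSE)) {
    hp <- generate_haplotype_paths(b2$build, row)
    for (i in seq_along(hp$paths)) {
      buffer_add(buf, hp$paths[[i]], hp$metadata[i, , drop = FALSE])
    }
  }
  buffer_flush(buf)
  expect_gbwt_identical(res$index, buf$index)
})
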