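test_that("RepeatMasker parsing converts coordinates, strand and divergence", {
  path <- withr::local_tempfile(fileext = ".out")
  write_rm_fixture(path)
  ann <- read_repeatmasker_out(path)
  expect_equal(nrow(ann), 2)
  # 1-based inclusive 101..300 -> 0-based half-open [100, 300)
  expect_equal(ann$start[1], 100L)
  expect_equal(ann$end[1], 300L)
  expect_equal(ann$strand, c("+", "-"))     # C maps to -
  expect_equal(ann$D[1], 0.125)             # 12.5% -> 0.125
  expect_equal(ann$element_id, c("el1", "el2"))
})

test_that("RepeatMasker parser errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".out")
  writeLines(c("h1", "h2", "", "  225  1.0 0.0 0.0 chr1 10"), path)
  expect_error(read_repeatmasker_out(path), "line 4")
})

test_that("empty RepeatMasker file after headers yields an empty table", {
  path <- withr::local_tempfile(fileext = ".out")
  writeLines(c("h1", "h2", ""), path)
  expect_equal(nrow(read_repeatmasker_out(path)), 0)
})

test_that("RepeatMasker write/read round trip is the identity", {
  path <- withr::local_tempfile(fileext = ".out")
  write_rm_fixture(path)
  ann <- read_repeatmasker_out(path)
  path2 <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker_out(ann, path2)
  ann2 <- read_repeatmasker_out(path2)
  expect_equal(ann2[, c("element_id", "chrom", "start", "end", "strand",
                        "subfamily", "D")],
               ann[, c("element_id", "chrom", "start", "end", "strand",
                       "subfamily", "D")])
})

test_that("extract_sequence is strand-aware with the documented orientation", {
  genome <- c(chrX = paste0("GG", "CTTTCTTTATTTATTT", "GG"))
  # minus-strand read of the reference slice gives the gene-coding strand
  expect_equal(extract_sequence(genome, "chrX", 2L, 18L, "-"), vwa8_insert_gene)
  expect_equal(extract_sequence(genome, "chrX", 2L, 18L, "+"), vwa8_insert_ref)
  expect_error(extract_sequence(genome, "chrZ", 0L, 5L), "unknown chromosome")
  expect_error(extract_sequence(genome, "chrX", 10L, 99L), "out of bounds")
})

test_that("reverse complement is an involution and length is preserved", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(sample(5:80, 1))
    genome <- c(c1 = s)
    fwd <- extract_sequence(genome, "c1", 0L, nchar(s), "+")
    rev <- extract_sequence(genome, "c1", 0L, nchar(s), "-")
    expect_equal(nchar(rev), nchar(s))
    expect_equal(fwd, s)
    expect_equal(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev))), s)
  }
})

test_that("gene feature derivation: introns are per-gene exon gaps", {
  # single-exon gene -> no introns
  f1 <- gene_features(
    genes = tibble::tibble(chrom = "c", start = 0L, end = 100L,
                           strand = "+", gene_id = "g1"),
    exons = tibble::tibble(chrom = "c", start = 0L, end = 100L,
                           strand = "+", gene_id = "g1")
  )
  expect_equal(nrow(f1$introns), 0)
  # exons [0,100) and [200,300) -> intron [100,200)
  f2 <- gene_features(
    genes = tibble::tibble(chrom = "c", start = 0L, end = 300L,
                           strand = "+", gene_id = "g1"),
    exons = tibble::tibble(chrom = "c", start = c(0L, 200L),
                           end = c(100L, 300L), strand = "+", gene_id = "g1")
  )
  expect_equal(f2$introns$start, 100L)
  expect_equal(f2$introns$end, 200L)
})

test_that("intergenic regions equal the per-base complement of gene spans", {
  genes <- tibble::tibble(chrom = "c",
                          start = c(100L, 250L), end = c(300L, 500L),
                          strand = "+", gene_id = c("g1", "g2"))  # overlapping
  f <- gene_features(genes, exons = genes, chrom_lengths = c(c = 1000L))
  # brute-force complement over base positions
  covered <- logical(1000)
  for (i in seq_len(nrow(genes))) {
    covered[(genes$start[i] + 1):genes$end[i]] <- TRUE
  }
  inter <- logical(1000)
  for (i in seq_len(nrow(f$intergenic))) {
    inter[(f$intergenic$start[i] + 1):f$intergenic$end[i]] <- TRUE
  }
  expect_equal(inter, !covered)
})

test_that("GFF3 writer/reader round trip preserves features", {
  feats <- make_gene_models(c(chr1 = 20000L, chr2 = 15000L),
                            n_genes = 6, seed = 5)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feats, path)
  back <- read_gene_features(path)
  ord <- function(d) d[order(d$chrom, d$start, d$end), c("chrom", "start", "end", "gene_id")]
  for (nm in c("genes", "exons", "cds", "utr5", "utr3")) {
    expect_equal(as.data.frame(ord(back[[nm]])),
                 as.data.frame(ord(feats[[nm]])), ignore_attr = TRUE)
  }
  expect_equal(as.data.frame(ord(back$introns)),
               as.data.frame(ord(feats$introns)), ignore_attr = TRUE)
})

test_that("tail table round trips losslessly, including empty tails", {
  set.seed(21)
  n <- 100
  rec <- tibble::tibble(
    element_id = sprintf("el%03d", 1:n),
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    start = as.integer(sample(1e6, n)),
    end = NA_integer_, strand = sample(c("+", "-"), n, TRUE),
    subfamily = sample(c("SINEA1", "SINEB1"), n, TRUE),
    method = sample(c("cutoff_exact", "cutoff_mismatch1", "fallback"), n, TRUE),
    tail_seq = vapply(1:n, function(i) random_dna(sample(0:40, 1)), character(1)),
    category = sample(tail_categories(), n, TRUE),
    D = round(runif(n, 0, 0.4), 4), K = NA_real_,
    age_my = NA_real_, age_bin = NA_character_
  )
  rec$end <- rec$start + nchar(rec$tail_seq) + 1L
  rec$tail_seq[1] <- ""   # explicit empty field must survive
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tail_table(rec, path)
  back <- read_tail_table(path)
  expect_equal(as.data.frame(back), as.data.frame(rec[, names(back)]),
               ignore_attr = TRUE)
})

test_that("tail table: empty input writes a header-only file; bad header errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tail_table(tibble::tibble(element_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  strand = character()), path)
  expect_equal(length(readLines(path)), 1)
  expect_equal(nrow(read_tail_table(path)), 0)
  writeLines("a\tb\tc", path)
  expect_error(read_tail_table(path), "header mismatch")
})
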