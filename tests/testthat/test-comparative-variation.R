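test_that("PAF read/write round trips and cigars parse", {
  paf <- tibble::tibble(
    qname = "v_chr1", qlen = 516L, qstart = 0L, qend = 516L, strand = "+",
    tname = "chr1", tlen = 500L, tstart = 0L, tend = 500L,
    nmatch = 500L, alnlen = 516L, mapq = 60L, cigar = "200M16I300M"
  )
  path <- withr::local_tempfile(fileext = ".paf")
  write_paf(paf, path)
  back <- read_paf(path)
  expect_equal(as.data.frame(back), as.data.frame(paf))
  ops <- parse_cigar("200M16I300M")
  expect_equal(ops$op, c("M", "I", "M"))
  expect_equal(ops$len, c(200L, 16L, 300L))
  expect_error(parse_cigar("12Q"), "malformed")
  expect_error(parse_cigar(NA_character_), "empty")
})

test_that("liftover through a self-alignment is the identity", {
  g <- Biostrings::DNAStringSet(c(chr1 = random_dna(800, seed = 2)))
  self <- make_variant_assembly(g, NULL)
  set.seed(6)
  for (i in 1:20) {
    s <- sample(0:700, 1); e <- s + sample(1:80, 1)
    lift <- liftover_interval("chr1", s, e, self$paf)
    expect_equal(c(lift$start, lift$end), c(s, e))
  }
})

test_that("an upstream insertion shifts downstream loci by its length", {
  g <- Biostrings::DNAStringSet(c(chr1 = random_dna(600, seed = 8)))
  va <- make_variant_assembly(
    g, tibble::tibble(chrom = "chr1", pos = 200L, type = "ins",
                      seq = vwa8_insert_ref, len = NA_integer_))
  expect_equal(va$paf$cigar, "200M16I400M")
  lift <- liftover_interval("chr1", 300L, 330L, va$paf)
  expect_equal(c(lift$start, lift$end), c(316L, 346L))
  # upstream locus unchanged
  lift0 <- liftover_interval("chr1", 50L, 80L, va$paf)
  expect_equal(c(lift0$start, lift0$end), c(50L, 80L))
})

test_that("loci inside deleted blocks are unmapped; flanking loci shift", {
  g <- Biostrings::DNAStringSet(c(chr1 = random_dna(600, seed = 9)))
  vd <- make_variant_assembly(
    g, tibble::tibble(chrom = "chr1", pos = 200L, type = "del",
                      seq = NA_character_, len = 50L))
  expect_equal(nrow(liftover_interval("chr1", 210L, 230L, vd$paf)), 0)
  lift <- liftover_interval("chr1", 300L, 330L, vd$paf)
  expect_equal(c(lift$start, lift$end), c(250L, 280L))
})

test_that("liftover reproduces every planted edit's predicted shift", {
  g <- Biostrings::DNAStringSet(c(chr1 = random_dna(2000, seed = 10)))
  edits <- tibble::tibble(
    chrom = "chr1", pos = c(300L, 800L, 1400L),
    type = c("ins", "del", "ins"),
    seq = c("ACGTACGT", NA, "TTTT"), len = c(NA, 20L, NA)
  )
  va <- make_variant_assembly(g, edits)
  # cumulative shift after each edit: +8, -20, +4
  probes <- tibble::tibble(start = c(100L, 500L, 1000L, 1600L),
                           shift = c(0L, 8L, -12L, -8L))
  for (i in seq_len(nrow(probes))) {
    lift <- liftover_interval("chr1", probes$start[i], probes$start[i] + 10L,
                              va$paf)
    expect_equal(lift$start, probes$start[i] + probes$shift[i])
  }
  # the edited sequence around a lifted locus is the reference sequence
  lift <- liftover_interval("chr1", 1600L, 1650L, va$paf)
  expect_equal(
    extract_sequence(va$genome, lift$chrom, lift$start, lift$end, "+"),
    extract_sequence(g, "chr1", 1600L, 1650L, "+"))
})

test_that("global alignment: identical sequences score 2 per base, gapless", {
  s <- "ACGTACGTACGTACGT"
  al <- align_global(s, s)
  expect_equal(al$score, 2 * nchar(s))
  expect_equal(al$a_aln, s)
  expect_equal(al$b_aln, s)
  expect_error(align_global("", "ACGT"), "empty")
})

test_that("a 16-bp insertion aligns as a single 16-column gap in the reference row", {
  ref <- paste0("GGATCCA", strrep("A", 12), "TGGATC")
  var <- paste0(substr(ref, 1, 12), vwa8_insert_ref, substr(ref, 13, nchar(ref)))
  al <- align_global(ref, var)
  gaps <- gregexpr("-+", al$a_aln)[[1]]
  expect_equal(length(gaps), 1)
  expect_equal(attr(gaps, "match.length"), 16L)
  expect_false(grepl("-", al$b_aln))
})

test_that("self-alignment score dominates and matches an independent aligner", {
  set.seed(12)
  for (i in 1:10) {
    a <- random_dna(sample(20:60, 1))
    b <- mutate_seq(random_dna(nchar(a)), 0)   # unrelated
    expect_gte(align_global(a, a)$score, align_global(a, b)$score)
    # independent oracle: Biostrings pairwise alignment, same scoring scheme
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                                    baseOnly = TRUE)
    ref_score <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = 4, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(align_global(a, b)$score, ref_score)
  }
})

test_that("polymorphism calls follow the documented precedence", {
  ref <- paste0("GATC", strrep("A", 20), "GATC")
  # all identical
  same <- setNames(rep(ref, 9), paste0("a", 1:9))
  expect_equal(call_polymorphism("L1", ref, same)$call, "identical")
  # one assembly unmapped
  miss <- same; miss[3] <- NA
  expect_equal(call_polymorphism("L2", ref, miss)$call, "presence_absence")
  # the printed 16-bp insertion in one of nine assemblies
  var <- paste0(substr(ref, 1, 14), vwa8_insert_ref,
                substr(ref, 15, nchar(ref)))
  nine <- same; nine[9] <- var
  pc <- call_polymorphism("L3", ref, nine)
  expect_equal(pc$call, "length_variant")
  expect_equal(pc$per_assembly[[1]]$length_delta[9], 16L)
  # same length, different repeat structure
  comp <- setNames(c(rep(ref, 2), paste0("GATC", strrep("AT", 10), "GATC")),
                   paste0("a", 1:3))
  pc2 <- call_polymorphism("L4", ref, comp)
  expect_equal(pc2$call, "composition_change")
  expect_error(call_polymorphism("L5", ref, character(0)), "assemblies")
})

test_that("compare_tail_loci lifts, extracts and calls across assemblies", {
  sim <- plant_genome(default_plant_specs(n_per = 2L), genome_length = 20000L,
                      seed = 33)
  tails <- extract_tails(sim$annotations, sim$genome)
  locus <- tails[1, ]
  # variant 1: identical; variant 2: 16-bp insertion inside the tail
  v1 <- make_variant_assembly(sim$genome, NULL, name = "v1")
  mid <- as.integer((locus$start + locus$end) %/% 2)
  v2 <- make_variant_assembly(
    sim$genome, tibble::tibble(chrom = locus$chrom, pos = mid, type = "ins",
                               seq = vwa8_insert_ref, len = NA_integer_),
    name = "v2")
  calls <- compare_tail_loci(
    locus, sim$genome,
    assemblies = list(v1 = v1$genome, v2 = v2$genome),
    pafs = list(v1 = v1$paf, v2 = v2$paf))
  expect_equal(calls$call, "length_variant")
  pa <- calls$per_assembly[[1]]
  expect_equal(pa$length_delta[pa$assembly == "v2"], 16L)
  expect_equal(pa$length_delta[pa$assembly == "v1"], 0L)
})
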