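test_that("build_mrna splices exons 5'->3' and honours strand", {
  gen <- c(chrA = "AAACCCGGGTTTACGTACGTAAACCCGGGTTT")
  one <- tibble::tibble(chrom = "chrA", start = 3L, end = 12L)
  expect_equal(build_mrna(gen, one, "+"), "CCCGGGTTT")
  # hand-spliced two-exon minus-strand oracle
  two <- tibble::tibble(chrom = "chrA", start = c(0L, 20L), end = c(10L, 30L))
  spliced_fwd <- paste0(substr(gen, 1, 10), substr(gen, 21, 30))
  expect_equal(build_mrna(gen, two, "-"),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(spliced_fwd))))
})

test_that("insertion edits lengthen the mRNA and shift only downstream bases", {
  gen <- c(chrB = random_dna(120, seed = 41))
  ex <- tibble::tibble(chrom = "chrB", start = c(0L, 60L), end = c(40L, 110L))
  edits <- tibble::tibble(chrom = "chrB", pos = 80L, insert = vwa8_insert_ref)
  ref <- build_mrna(gen, ex, "+")
  var <- build_mrna(gen, ex, "+", edits)
  expect_equal(nchar(var), nchar(ref) + 16L)
  # upstream of the insertion point (exon1 40bp + 20bp of exon2) unchanged
  expect_equal(substr(var, 1, 60), substr(ref, 1, 60))
  expect_equal(substr(var, 61, 76), vwa8_insert_ref)
  # edit outside every exon: warning, mRNA unchanged
  bad <- tibble::tibble(chrom = "chrB", pos = 50L, insert = "ACGT")
  expect_warning(unchanged <- build_mrna(gen, ex, "+", bad), "outside")
  expect_equal(unchanged, ref)
})

test_that("build_mrna length = sum of exon lengths + insertions", {
  set.seed(52)
  for (i in 1:10) {
    gen <- c(g = random_dna(300))
    n_ex <- sample(1:3, 1)
    starts <- sort(sample(seq(0, 240, by = 60), n_ex))
    ex <- tibble::tibble(chrom = "g", start = starts, end = starts + 50L)
    ins <- tibble::tibble(chrom = "g", pos = starts[1] + 10L,
                          insert = random_dna(sample(1:20, 1)))
    m <- build_mrna(gen, ex, sample(c("+", "-"), 1), ins)
    expect_equal(nchar(m), sum(ex$end - ex$start) + nchar(ins$insert))
  }
})

test_that("translation uses the standard code, stops at the first stop", {
  expect_equal(translate_orf("ATG"), "M")
  expect_equal(translate_orf("ATGTAA"), "M")
  expect_equal(translate_orf("ATGAAATAA"), "MK")
  expect_equal(translate_orf("ATGNNNAAA"), "MXK")
  expect_error(translate_orf("ATGA"), "multiple of 3")
  # independent oracle: Biostrings translation over random in-frame sequences
  set.seed(61)
  for (i in 1:10) {
    s <- random_dna(3 * sample(5:30, 1))
    ours <- translate_orf(s)
    bs <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                             no.init.codon = TRUE))
    bs <- sub("\\*.*$", "", bs)
    expect_equal(ours, bs)
  }
})

test_that("the longest ORF is found across six frames", {
  o <- find_longest_orf("ATGAAATAA")
  expect_equal(o$protein, "MK")
  expect_equal(o$strand, "+")
  # plant the longest ORF on the reverse strand
  fwd_orf <- paste0("ATG", strrep("GCT", 10), "TAA")
  s <- paste0("CCCC", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd_orf))), "CCCC")
  o2 <- find_longest_orf(s)
  expect_equal(o2$strand, "-")
  expect_equal(o2$protein, paste0("M", strrep("A", 10)))
  expect_error(find_longest_orf("AT"), "shorter")
})

test_that("ORF finder agrees with exhaustive six-frame enumeration", {
  brute <- function(s) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    best <- 0
    for (seqs in list(s, rc)) {
      for (fr in 0:2) {
        i <- 1 + fr
        while (i + 2 <= nchar(seqs)) {
          if (substr(seqs, i, i + 2) == "ATG") {
            j <- i
            while (j + 2 <= nchar(seqs)) {
              cd <- substr(seqs, j, j + 2)
              if (cd %in% c("TAA", "TAG", "TGA")) {
                best <- max(best, j + 2 - i + 1)
                break
              }
              j <- j + 3
            }
          }
          i <- i + 3
        }
      }
    }
    best
  }
  set.seed(77)
  for (i in 1:15) {
    s <- random_dna(300)
    o <- find_longest_orf(s)
    expect_equal(if (is.null(o)) 0L else nchar(o$orf_seq), brute(s), info = s)
  }
})

test_that("protein comparison reports identity, divergence point and frameshift", {
  p <- strrep("MKLV", 10)
  cmp <- compare_proteins(p, p, insertion_len = 18)
  expect_equal(cmp$identity_pct, 100)
  expect_true(is.na(cmp$first_divergent_pos))
  expect_false(cmp$frameshift)          # 18 mod 3 == 0

  # diverges only after position k = 20
  q <- paste0(substr(p, 1, 20), "WWWWWWWWWWWWWWWWWWWW")
  cmp2 <- compare_proteins(p, q, insertion_len = 16)
  expect_equal(cmp2$first_divergent_pos, 21L)
  expect_true(cmp2$frameshift)          # 16 mod 3 == 1
  expect_equal(cmp2$insertion_mod3, 1)
  expect_error(compare_proteins("", "M", 1), "empty")
})

test_that("an in-frame insertion never changes residues upstream of its site", {
  set.seed(91)
  for (i in 1:8) {
    body <- strrep("GCT", 30)
    gen <- c(g = paste0("ATG", body, "TAATT"))
    ex <- tibble::tibble(chrom = "g", start = 0L, end = nchar(gen[["g"]]))
    pos <- as.integer(3 + 3 * sample(5:25, 1))
    ins <- paste(rep(c("GAA"), sample(1:3, 1)), collapse = "")
    rep_row <- cds_impact_report(gen, ex, "+",
                                 tibble::tibble(chrom = "g", pos = pos,
                                                insert = ins))
    expect_false(rep_row$frameshift)
    k <- (pos - 3) / 3     # residues upstream of the insertion point
    expect_equal(substr(rep_row$protein_var, 1, k),
                 substr(rep_row$protein_ref, 1, k))
    expect_equal(rep_row$len_var, rep_row$len_ref + nchar(ins) / 3)
  }
})

test_that("a frameshifting tail insertion truncates and rewrites the C-terminus", {
  # reference: ATG + 40 codons + TAA; the trailer stops every reading frame
  body <- strrep("GCA", 40)
  gen <- c(g = paste0("ATG", body, "TAA", "CTAACTAACTAA", "CC"))
  ex <- tibble::tibble(chrom = "g", start = 0L, end = nchar(gen[["g"]]))
  rep_row <- cds_impact_report(
    gen, ex, "+",
    tibble::tibble(chrom = "g", pos = 63L, insert = vwa8_insert_ref))
  expect_true(rep_row$frameshift)
  expect_equal(rep_row$insertion_mod3, 1)
  expect_lt(rep_row$identity_pct, 100)
  expect_equal(rep_row$len_ref, 41L)               # M + 40 alanines
  # 21 residues (ATG + 20 codons) upstream of the insertion are preserved
  expect_equal(rep_row$first_divergent_pos, 22L)
  expect_equal(substr(rep_row$protein_var, 1, 21),
               substr(rep_row$protein_ref, 1, 21))
  expect_equal(rep_row$mrna_len_var, rep_row$mrna_len_ref + 16L)
})
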