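#' Reconstruct an mRNA from exons, applying insertion edits
#'
#' Exon slices are spliced in genomic order and reverse-complemented for `-`
#' strand transcripts, so the result reads 5' to 3' in transcript
#' orientation. Edits are insertions given in reference coordinates and
#' reference-strand orientation: `pos` is the 0-based genomic coordinate
#' before which `insert` is placed. Downstream coordinates shift
#' automatically because edits are applied per-exon before splicing. Edits
#' falling outside every exon are skipped with a warning.
#'
#' @param genome Genome ([Biostrings::DNAStringSet] or named character).
#' @param exons Tibble of exon intervals (`chrom`, `start`, `end`), 0-based
#'   half-open, non-overlapping.
#' @param strand Transcript strand, `+` or `-`.
#' @param edits Optional tibble of insertions: `chrom`, `pos`, `insert`.
#' @return mRNA sequence (character scalar).
#' @export
build_mrna <- function(genome, exons, strand = "+", edits = NULL) {
  genome <- as_dnastringset(genome)
  exons <- exons |> arrange(.data$chrom, .data$start)
  if (!is.null(edits) && nrow(edits)) {
    in_exon <- vapply(seq_len(nrow(edits)), function(i) {
      any(edits$chrom[i] == exons$chrom &
            edits$pos[i] >= exons$start & edits$pos[i] < exons$end)
    }, logical(1))
    if (any(!in_exon)) {
      warn(sprintf("%d edit(s) outside every exon were ignored", sum(!in_exon)))
      edits <- edits[in_exon, ]
    }
  }
  pieces <- vapply(seq_len(nrow(exons)), function(i) {
    ex <- exons[i, ]
    s <- extract_sequence(genome, ex$chrom, ex$start, ex$end, "+")
    if (!is.null(edits) && nrow(edits)) {
      e <- edits |>
        filter(.data$chrom == ex$chrom, .data$pos >= ex$start,
               .data$pos < ex$end) |>
        arrange(desc(.data$pos))
      for (k in seq_len(nrow(e))) {
        rel <- e$pos[k] - ex$start
        s <- paste0(substr(s, 1, rel), e$insert[k],
                    substr(s, rel + 1, nchar(s)))
      }
    }
    s
  }, character(1))
  mrna <- paste(pieces, collapse = "")
  if (strand == "-") mrna <- revcomp(mrna)
  mrna
}

#' Translate an in-frame nucleotide sequence
#'
#' Standard genetic code; translation stops at the first stop codon; codons
#' containing `N` become `X`.
#'
#' @param orf_seq Nucleotide sequence whose length is a multiple of 3.
#' @return Protein string (no stop symbol).
#' @export
translate_orf <- function(orf_seq) {
  if (nchar(orf_seq) %% 3 != 0) abort("ORF length not a multiple of 3")
  if (!nzchar(orf_seq)) return("")
  codons <- substring(orf_seq, seq(1, nchar(orf_seq), 3),
                      seq(3, nchar(orf_seq), 3))
  aa <- vapply(codons, function(cd) {
    if (grepl("N", cd)) return("X")
    unname(Biostrings::GENETIC_CODE[cd])
  }, character(1), USE.NAMES = FALSE)
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1)]
  paste(aa, collapse = "")
}

#' Find the longest open reading frame across six frames
#'
#' Scans the three forward frames and the three frames of the reverse
#' complement for spans `ATG ... {TAA, TAG, TGA}` and returns the longest
#' (ties: forward frames before reverse, then lower frame, then leftmost).
#'
#' @param mrna mRNA sequence (length >= 3).
#' @return `NULL` when no ORF exists, else a list: `strand` (`+`/`-`),
#'   `frame` (0-2, offset within that strand's sequence), `start`, `end`
#'   (0-based half-open within the scanned strand's sequence, stop codon
#'   included), `orf_seq`, `protein`.
#' @export
find_longest_orf <- function(mrna) {
  if (nchar(mrna) < 3) abort("sequence shorter than one codon")
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (std in c("+", "-")) {
    s <- if (std == "+") mrna else revcomp(mrna)
    for (fr in 0:2) {
      starts <- seq(1 + fr, nchar(s) - 2, by = 3)
      codons <- substring(s, starts, starts + 2)
      open_at <- NA_integer_
      for (k in seq_along(codons)) {
        if (is.na(open_at) && codons[k] == "ATG") open_at <- k
        if (!is.na(open_at) && codons[k] %in% stops) {
          len <- (k - open_at + 1) * 3
          if (is.null(best) || len > best$nt_len) {
            best <- list(strand = std, frame = fr,
                         start = starts[open_at] - 1L,
                         end = starts[k] + 2L, nt_len = len)
          }
          open_at <- NA_integer_
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  s <- if (best$strand == "+") mrna else revcomp(mrna)
  best$orf_seq <- substr(s, best$start + 1, best$end)
  best$protein <- translate_orf(best$orf_seq)
  best$nt_len <- NULL
  best
}

#' Compare a reference and a variant protein
#'
#' Global alignment (affine gaps, same scheme as [align_global()]); identity
#' is identities over alignment columns including gaps. The frameshift flag
#' derives from the inserted length modulo 3, and an internal stop in the
#' variant is reported through the shorter protein length, not treated as an
#' error.
#'
#' @param p_ref,p_var Protein sequences (non-empty).
#' @param insertion_len Length in bp of the causal insertion.
#' @return One-row tibble: `len_ref`, `len_var`, `identity_pct`,
#'   `first_divergent_pos` (1-based position of the first differing
#'   alignment column, in reference residue numbering; `NA` when identical),
#'   `frameshift` (logical), `insertion_mod3`.
#' @export
compare_proteins <- function(p_ref, p_var, insertion_len) {
  if (!nzchar(p_ref) || !nzchar(p_var)) abort("empty protein sequence")
  al <- align_global(p_ref, p_var)
  ra <- strsplit(al$a_aln, "")[[1]]; rb <- strsplit(al$b_aln, "")[[1]]
  same <- ra == rb
  ref_pos <- cumsum(ra != "-")
  first_div <- if (all(same)) NA_integer_ else {
    i <- which(!same)[1]
    # in reference residue numbering; an inserted (gap-in-reference) column
    # means divergence begins at the next reference residue
    if (ra[i] == "-") ref_pos[i] + 1L else max(ref_pos[i], 1L)
  }
  tibble(
    len_ref = nchar(p_ref), len_var = nchar(p_var),
    identity_pct = 100 * sum(same & ra != "-") / length(ra),
    first_divergent_pos = first_div,
    frameshift = insertion_len %% 3 != 0,
    insertion_mod3 = insertion_len %% 3
  )
}

#' Report the coding impact of a tail insertion on one transcript
#'
#' Builds the reference and edited mRNAs, finds the longest ORF in each
#' across six frames, translates, and compares the proteins.
#'
#' @param genome Reference genome.
#' @param exons Exon tibble (`chrom`, `start`, `end`).
#' @param strand Transcript strand.
#' @param edits Insertion tibble (`chrom`, `pos`, `insert`).
#' @return One-row tibble: mRNA lengths, ORF/protein lengths for both
#'   alleles, plus the [compare_proteins()] columns.
#' @export
cds_impact_report <- function(genome, exons, strand, edits) {
  mrna_ref <- build_mrna(genome, exons, strand)
  mrna_var <- build_mrna(genome, exons, strand, edits)
  orf_ref <- find_longest_orf(mrna_ref)
  orf_var <- find_longest_orf(mrna_var)
  if (is.null(orf_ref) || is.null(orf_var)) {
    abort("no open reading frame found in one of the alleles")
  }
  ins_len <- sum(nchar(edits$insert))
  cmp <- compare_proteins(orf_ref$protein, orf_var$protein, ins_len)
  dplyr::bind_cols(
    tibble(mrna_len_ref = nchar(mrna_ref), mrna_len_var = nchar(mrna_var),
           orf_strand_ref = orf_ref$strand, orf_strand_var = orf_var$strand,
           protein_ref = orf_ref$protein, protein_var = orf_var$protein),
    cmp
  )
}
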