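#' Read a PAF alignment file
#'
#' Parses the 12 mandatory PAF columns plus the `cg:Z:` cigar tag (required
#' for liftover). Coordinates are 0-based half-open, as in the format. The
#' package convention is target = reference assembly, query = other assembly.
#'
#' @param path PAF file path.
#' @return Tibble: `qname`, `qlen`, `qstart`, `qend`, `strand`, `tname`,
#'   `tlen`, `tstart`, `tend`, `nmatch`, `alnlen`, `mapq`, `cigar`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 12) abort(sprintf("malformed PAF row at line %d", i))
    cg <- grep("^cg:Z:", f, value = TRUE)
    tibble(
      qname = f[1], qlen = as.integer(f[2]),
      qstart = as.integer(f[3]), qend = as.integer(f[4]),
      strand = f[5], tname = f[6], tlen = as.integer(f[7]),
      tstart = as.integer(f[8]), tend = as.integer(f[9]),
      nmatch = as.integer(f[10]), alnlen = as.integer(f[11]),
      mapq = as.integer(f[12]),
      cigar = if (length(cg)) sub("^cg:Z:", "", cg[1]) else NA_character_
    )
  })
  bind_rows(rows)
}

#' Write alignments in PAF format
#'
#' @param paf Tibble as returned by [read_paf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  lines <- vapply(seq_len(nrow(paf)), function(i) {
    p <- paf[i, ]
    paste(c(p$qname, p$qlen, p$qstart, p$qend, p$strand, p$tname, p$tlen,
            p$tstart, p$tend, p$nmatch, p$alnlen, p$mapq,
            if (!is.na(p$cigar)) paste0("cg:Z:", p$cigar)),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a cigar string into operation runs
#'
#' @param cigar Cigar string with `M`/`I`/`D`/`=`/`X` operations (`=`/`X`
#'   are treated as `M`).
#' @return Tibble with `op` and `len`.
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) abort("empty cigar")
  m <- gregexpr("\\d+[MIDX=]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDX=]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) {
    abort(sprintf("malformed cigar '%s'", cigar))
  }
  op <- substr(toks, nchar(toks), nchar(toks))
  op[op %in% c("=", "X")] <- "M"
  tibble(op = op, len = as.integer(substr(toks, 1, nchar(toks) - 1)))
}

# Map one 0-based target (reference) position through one PAF record.
# Returns the 0-based query coordinate, or NA if the position falls in a
# deletion or outside the aligned span.
map_position_paf <- function(rec, pos) {
  if (pos < rec$tstart || pos >= rec$tend) return(NA_integer_)
  ops <- parse_cigar(rec$cigar)
  dt <- pos - rec$tstart
  t_off <- 0L; q_off <- 0L
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    t_use <- if (op %in% c("M", "D")) len else 0L
    q_use <- if (op %in% c("M", "I")) len else 0L
    if (dt < t_off + t_use) {
      if (op == "D") return(NA_integer_)
      within <- dt - t_off
      qf <- q_off + within
      return(if (rec$strand == "+") rec$qstart + qf else rec$qend - qf - 1L)
    }
    t_off <- t_off + t_use
    q_off <- q_off + q_use
  }
  NA_integer_
}

#' Lift a reference interval into another assembly through PAF alignments
#'
#' Walks the cigar of the alignment covering the interval and maps both
#' endpoints. The lift fails (returns a zero-row tibble) when either endpoint
#' falls in a deleted block, outside every alignment, or the two endpoints
#' map through different alignment records. Strand-reversed alignments flip
#' the interval.
#'
#' @param chrom,start,end Reference interval (0-based half-open).
#' @param paf PAF tibble ([read_paf()]) with target = reference.
#' @return One-row tibble `chrom`, `start`, `end`, `strand` (strand of the
#'   alignment through which the interval was lifted), or a zero-row tibble
#'   when unmapped.
#' @export
liftover_interval <- function(chrom, start, end, paf) {
  stopifnot(end > start)
  unmapped <- tibble(chrom = character(), start = integer(),
                     end = integer(), strand = character())
  cand <- paf |> filter(.data$tname == chrom, .data$tstart <= start,
                        .data$tend >= end)
  for (i in seq_len(nrow(cand))) {
    rec <- cand[i, ]
    a <- map_position_paf(rec, start)
    b <- map_position_paf(rec, end - 1L)
    if (is.na(a) || is.na(b)) next
    lo <- min(a, b); hi <- max(a, b) + 1L
    return(tibble(chrom = rec$qname, start = lo, end = hi,
                  strand = rec$strand))
  }
  unmapped
}

#' Pairwise global alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment used in place of a multiple aligner for
#' per-locus tail comparison: deterministic, exact, adequate for a handful of
#' short sequences. A gap of length L costs `gap_open + L * gap_extend`.
#' Traceback tie-break prefers the diagonal, then a gap in `b`, then a gap in
#' `a`, so results are reproducible.
#'
#' @param a,b Sequences (any single-letter alphabet; DNA or protein).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters
#'   (defaults +2, -2, -4, -1).
#' @return List with `a_aln`, `b_aln` (gapped strings of equal length) and
#'   `score`.
#' @export
align_global <- function(a, b, match = 2, mismatch = -2,
                         gap_open = -4, gap_extend = -1) {
  if (!nzchar(a)) abort("empty reference sequence in alignment")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in a (consumes b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- gap_open + (i - 1) * gap_extend
  if (m > 0) for (j in 2:(m + 1)) Y[1, j] <- gap_open + (j - 1) * gap_extend
  if (m > 0 && n > 0) {
    for (i in 2:(n + 1)) {
      for (j in 2:(m + 1)) {
        s <- if (av[i - 1] == bv[j - 1] && av[i - 1] != "N") match else mismatch
        M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
        X[i, j] <- max(M[i - 1, j] + gap_open + gap_extend,
                       X[i - 1, j] + gap_extend)
        Y[i, j] <- max(M[i, j - 1] + gap_open + gap_extend,
                       Y[i, j - 1] + gap_extend)
      }
    }
  }
  # traceback
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))  # 1=M, 2=X, 3=Y
  ra <- character(0); rb <- character(0)
  score <- c(M[i, j], X[i, j], Y[i, j])[state]
  while (i > 1 || j > 1) {
    if (state == 1) {
      s <- if (av[i - 1] == bv[j - 1] && av[i - 1] != "N") match else mismatch
      ra <- c(av[i - 1], ra); rb <- c(bv[j - 1], rb)
      # predecessor is the best of the three states; ties prefer M, then X
      state <- which.max(c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]))
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      ra <- c(av[i - 1], ra); rb <- c("-", rb)
      state <- if (M[i - 1, j] + gap_open + gap_extend >= X[i - 1, j] + gap_extend) 1 else 2
      if (i == 2 && j == 1) state <- 1
      i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(bv[j - 1], rb)
      state <- if (M[i, j - 1] + gap_open + gap_extend >= Y[i, j - 1] + gap_extend) 1 else 3
      if (j == 2 && i == 1) state <- 1
      j <- j - 1
    }
  }
  list(a_aln = paste(ra, collapse = ""), b_aln = paste(rb, collapse = ""),
       score = score)
}

#' Align non-reference locus sequences to the reference (star layout)
#'
#' @param ref_seq Reference tail sequence.
#' @param other_seqs Named character vector; `NA` marks an absent/unmapped
#'   assembly.
#' @param ... Scoring parameters passed to [align_global()].
#' @return Tibble per assembly: `assembly`, `present`, `score`, `aligned_ref`,
#'   `aligned_seq`, `ref_aligned_frac` (fraction of reference bases aligned
#'   to a base rather than a gap), `net_indel` (length difference vs
#'   reference), `identity_pct`.
#' @export
align_locus <- function(ref_seq, other_seqs, ...) {
  if (!nzchar(ref_seq)) abort("empty reference sequence")
  rows <- purrr::imap(other_seqs, function(s, nm) {
    if (is.na(s)) {
      return(tibble(assembly = nm, present = FALSE, score = NA_real_,
                    aligned_ref = NA_character_, aligned_seq = NA_character_,
                    ref_aligned_frac = 0, net_indel = NA_integer_,
                    identity_pct = NA_real_))
    }
    al <- align_global(ref_seq, s, ...)
    ra <- strsplit(al$a_aln, "")[[1]]; rb <- strsplit(al$b_aln, "")[[1]]
    cols <- length(ra)
    tibble(
      assembly = nm, present = TRUE, score = al$score,
      aligned_ref = al$a_aln, aligned_seq = al$b_aln,
      ref_aligned_frac = sum(ra != "-" & rb != "-") / nchar(ref_seq),
      net_indel = nchar(s) - nchar(ref_seq),
      identity_pct = 100 * sum(ra == rb & ra != "-") / cols
    )
  })
  bind_rows(rows)
}

#' Call a tail polymorphism across assemblies at one locus
#'
#' Call precedence formalises the published variant types:
#' `presence_absence` when any assembly is unmapped/absent or aligns less
#' than `presence_min_frac` of the reference tail; otherwise
#' `length_variant` when any assembly shows a net indel of at least 1 bp
#' within the tail; otherwise `composition_change` when the assigned tail
#' categories differ; otherwise `identical`.
#'
#' @param locus_id Locus identifier carried into the output.
#' @param ref_seq Reference tail sequence (element orientation).
#' @param other_seqs Named character vector of tail sequences per assembly
#'   (`NA` = unmapped/absent). At least one non-reference assembly required.
#' @param config [classifier_config()] used to categorise each sequence.
#' @param presence_min_frac Minimum aligned fraction of the reference tail
#'   for an assembly to count as present (default 0.5).
#' @param ... Scoring parameters for [align_global()].
#' @return One-row tibble: `locus_id`, `call`, `n_assemblies`,
#'   `ref_category`, and a `per_assembly` list-column (the [align_locus()]
#'   table plus per-assembly `category` and `length_delta`).
#' @export
call_polymorphism <- function(locus_id, ref_seq, other_seqs,
                              config = classifier_config(),
                              presence_min_frac = 0.5, ...) {
  if (length(other_seqs) < 1) abort("need at least 2 assemblies (reference + 1)")
  aln <- align_locus(ref_seq, other_seqs, ...)
  aln$category <- ifelse(is.na(aln$aligned_seq), NA_character_,
                         classify_tail(ifelse(is.na(other_seqs), "", other_seqs),
                                       config))
  aln$length_delta <- aln$net_indel
  ref_category <- classify_tail(ref_seq, config)

  missing_like <- !aln$present | aln$ref_aligned_frac < presence_min_frac
  call <- if (any(missing_like)) {
    "presence_absence"
  } else if (any(abs(aln$net_indel) >= 1)) {
    "length_variant"
  } else if (any(aln$category != ref_category)) {
    "composition_change"
  } else {
    "identical"
  }
  tibble(locus_id = locus_id, call = call,
         n_assemblies = length(other_seqs) + 1L,
         ref_category = ref_category,
         per_assembly = list(aln))
}

#' Compare tail loci across assemblies
#'
#' End-to-end comparative step: for each locus, lift the reference tail
#' interval into every assembly through its PAF alignments, extract the tail
#' sequence in element orientation, and call the polymorphism type.
#'
#' @param loci Tail tibble (`element_id`, `chrom`, `start`, `end`, `strand`,
#'   `tail_seq` optional - recomputed from `ref_genome` when absent).
#' @param ref_genome Reference genome ([Biostrings::DNAStringSet]).
#' @param assemblies Named list of genomes.
#' @param pafs Named list of PAF tibbles (same names; target = reference).
#' @param config A [classifier_config()].
#' @param presence_min_frac See [call_polymorphism()].
#' @return Tibble of per-locus calls (one row per locus).
#' @export
compare_tail_loci <- function(loci, ref_genome, assemblies, pafs,
                              config = classifier_config(),
                              presence_min_frac = 0.5) {
  stopifnot(identical(sort(names(assemblies)), sort(names(pafs))))
  rows <- purrr::pmap(
    loci[, c("element_id", "chrom", "start", "end", "strand")],
    function(element_id, chrom, start, end, strand) {
      ref_seq <- extract_sequence(ref_genome, chrom, start, end, strand)
      seqs <- vapply(names(assemblies), function(nm) {
        lift <- liftover_interval(chrom, start, end, pafs[[nm]])
        if (nrow(lift) == 0) return(NA_character_)
        # element orientation: locus strand, flipped when the alignment is
        # strand-reversed
        s <- if (lift$strand == "-") {
          if (strand == "+") "-" else "+"
        } else strand
        extract_sequence(assemblies[[nm]], lift$chrom, lift$start, lift$end, s)
      }, character(1))
      call_polymorphism(element_id, ref_seq, seqs, config, presence_min_frac)
    }
  )
  bind_rows(rows)
}
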