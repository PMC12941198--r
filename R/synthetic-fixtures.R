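# Run code under a temporary RNG state so generators are pure functions of
# (spec, seed) without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random background DNA
#'
#' @param n Length in bp.
#' @param gc GC content (default 0.42, pig-like).
#' @param seed Optional integer seed.
#' @return Character scalar.
#' @export
random_dna <- function(n, gc = 0.42, seed = NULL) {
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  })
}

#' Mutate a sequence by random substitutions
#'
#' Each base is substituted with probability `d`, uniformly over the three
#' alternative bases (substitution-only model: no indels, so planted tail
#' boundaries stay well defined).
#'
#' @param seq Uppercase sequence.
#' @param d Per-base substitution probability in `[0, 0.5]`.
#' @param seed Optional integer seed.
#' @return Mutated sequence.
#' @export
mutate_seq <- function(seq, d, seed = NULL) {
  stopifnot(d >= 0, d <= 0.5)
  if (d == 0 || !nzchar(seq)) return(seq)
  with_seed(seed, {
    v <- strsplit(seq, "")[[1]]
    hit <- runif(length(v)) < d
    for (i in which(hit)) {
      v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    }
    paste(v, collapse = "")
  })
}

hamming_divergence <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  mean(va != vb)
}

#' Construct a tail sequence guaranteed to classify as a category
#'
#' Deterministic construction per category (tandem tiling for `(motif)n`,
#' all-A for A-rich, a motif-mixture unit for composites, A-free random
#' sequence for Other), followed by a verify loop against [classify_tail()]
#' with bounded retries. Errors when the requested length cannot satisfy the
#' category's criterion (e.g. a 5-mer tandem needs at least 10 bp).
#'
#' @param category A label from [tail_categories()].
#' @param length Tail length (>= 1).
#' @param seed Optional seed (used for Other and retry jitter).
#' @param config [classifier_config()] used for verification.
#' @param max_tries Retry bound (default 25).
#' @return Tail sequence of the requested length.
#' @export
make_tail <- function(category, length, seed = NULL,
                      config = classifier_config(), max_tries = 25) {
  stopifnot(length >= 1, category %in% tail_categories())
  sers <- an_series_motifs()
  tile <- function(unit, n) substr(strrep(unit, ceiling(n / nchar(unit))), 1, n)
  build <- function(try) {
    if (category == "A-rich") return(strrep("A", length))
    if (category == "Other") {
      return(with_seed(if (is.null(seed)) NULL else seed + try,
                       paste(sample(c("C", "G", "T"), length, replace = TRUE),
                             collapse = "")))
    }
    if (grepl("composite$", category)) {
      ser <- sub("-composite", "", category)
      m <- sers[[ser]]
      return(tile(paste0(m[1], m[2], m[3]), length))
    }
    motif <- sub("^\\((.*)\\)n$", "\\1", category)
    tile(motif, length)
  }
  for (try in seq_len(max_tries)) {
    s <- build(try)
    if (classify_tail(s, config) == category) return(s)
  }
  abort(sprintf("cannot construct a %d bp tail classifying as %s",
                length, category))
}

# Synthetic SINE subfamily definitions: a deterministic consensus body ending
# in a subfamily-specific cutoff motif. Motifs match
# inst/extdata/cutoff_library_synthetic.tsv.
synthetic_cutoffs <- c(
  SINEA1 = "GGAGTTCGGT", SINEA2 = "GGAGTTCGGT", SINEA3 = "GGAGTTCGGT",
  SINEB1 = "CCTAGGTTCA", SINEB2 = "CCTAGGTTCA",
  SINEC1 = "TGGCGCAATC"
)

#' Synthetic consensus sequence of a subfamily
#'
#' Deterministic pseudo-random body (seeded by subfamily index) ending in the
#' subfamily's cutoff motif. Purely synthetic: not a biological consensus.
#'
#' @param subfamily One of the names of `synthetic_cutoffs`.
#' @param body_length Total body length including the cutoff (default 250).
#' @return Character scalar.
#' @export
synthetic_consensus <- function(subfamily, body_length = 250L) {
  if (!subfamily %in% names(synthetic_cutoffs)) {
    abort(sprintf("unknown synthetic subfamily '%s'", subfamily))
  }
  motif <- synthetic_cutoffs[[subfamily]]
  idx <- match(subfamily, names(synthetic_cutoffs))
  core <- random_dna(body_length - nchar(motif), gc = 0.45, seed = 77000 + idx)
  paste0(core, motif)
}

#' Plant SINE elements in a synthetic genome
#'
#' Generates a random background genome and inserts SINE copies of known
#' subfamily, divergence, strand and tail category at non-overlapping,
#' evenly spaced positions. Each element is a mutated copy of the synthetic
#' subfamily consensus (the cutoff motif is kept intact or mutated along with
#' the body, per `cutoff_intact`) followed by an unmutated tail constructed
#' with [make_tail()]. The emitted annotations carry the realised Hamming
#' divergence of the whole element, so annotation divergence and emitted
#' sequence agree exactly.
#'
#' @param specs Tibble with columns `subfamily`, `n`, `divergence`, `strand`,
#'   `category`, `tail_length`, `cutoff_intact` (one row per element group).
#' @param genome_length Background genome length (single chromosome `chrS`).
#' @param seed Integer seed; the generator is a pure function of
#'   `(specs, genome_length, seed)`.
#' @param chrom Chromosome name (default `"chrS"`).
#' @return List: `genome` ([Biostrings::DNAStringSet]), `annotations`
#'   (RepeatMasker-style tibble as from [read_repeatmasker_out()]), `truth`
#'   (per-element tibble: planted coordinates, strand, subfamily, realised
#'   divergence, tail boundary offset, genomic tail span, category and tail
#'   sequence).
#' @export
plant_genome <- function(specs, genome_length = 100000L, seed = 1L,
                         chrom = "chrS") {
  genome_length <- as.integer(genome_length)
  copies <- specs |>
    tidyr::uncount(.data$n, .id = "copy_i") |>
    mutate(element_id = sprintf("el%03d", row_number()))
  n_el <- nrow(copies)
  with_seed(seed, {
    background <- random_dna(genome_length, gc = 0.42)
    # elements in order, in evenly spaced slots with jitter
    elements <- purrr::pmap(copies, function(subfamily, divergence, strand,
                                             category, tail_length,
                                             cutoff_intact, element_id, ...) {
      cons <- synthetic_consensus(subfamily)
      motif <- synthetic_cutoffs[[subfamily]]
      mlen <- nchar(motif)
      body <- substr(cons, 1, nchar(cons) - mlen)
      mut_body <- mutate_seq(body, divergence)
      mut_motif <- if (cutoff_intact) motif else mutate_seq(motif, divergence)
      tail_seq <- make_tail(category, tail_length)
      el <- paste0(mut_body, mut_motif, tail_seq)
      orig <- paste0(cons, tail_seq)
      list(element_id = element_id, subfamily = subfamily, strand = strand,
           category = category, seq = el,
           tail_offset = nchar(cons),                 # element orientation
           tail_length = tail_length,
           realized_d = hamming_divergence(el, orig))
    })
    el_lens <- vapply(elements, function(e) nchar(e$seq), integer(1))
    slot <- genome_length %/% n_el
    if (any(el_lens + 2 > slot)) abort("genome too short for requested plants")
    offsets <- vapply(seq_len(n_el), function(i) {
      jitter_max <- slot - el_lens[i] - 1L
      (i - 1L) * slot + sample.int(jitter_max, 1)
    }, integer(1))

    gvec <- strsplit(background, "")[[1]]
    rows_ann <- list(); rows_truth <- list()
    for (i in seq_len(n_el)) {
      e <- elements[[i]]
      ins <- if (e$strand == "+") e$seq else revcomp(e$seq)
      start <- offsets[i]
      end <- start + nchar(ins)
      gvec[(start + 1):end] <- strsplit(ins, "")[[1]]
      gi <- tail_genomic_interval(start, end, e$strand,
                                  e$tail_offset, e$tail_length)
      rows_ann[[i]] <- tibble(
        element_id = e$element_id, chrom = chrom,
        start = start, end = end, strand = e$strand,
        subfamily = e$subfamily, class_family = "SINE/tRNA",
        D = e$realized_d, score = 225
      )
      rows_truth[[i]] <- tibble(
        element_id = e$element_id, chrom = chrom,
        start = start, end = end, strand = e$strand,
        subfamily = e$subfamily, D = e$realized_d,
        tail_offset = e$tail_offset,
        tail_start = gi$start, tail_end = gi$end,
        category = e$category,
        tail_seq = substr(e$seq, e$tail_offset + 1, nchar(e$seq))
      )
    }
    genome <- Biostrings::DNAStringSet(setNames(paste(gvec, collapse = ""), chrom))
    list(genome = genome, annotations = bind_rows(rows_ann),
         truth = bind_rows(rows_truth))
  })
}

#' Synthetic gene models
#'
#' Generates non-overlapping protein-coding gene models (1-4 exons with CDS
#' and flanking UTR pieces on the terminal exons) across the given
#' chromosomes, for exercising feature intersection.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @return A [gene_features()] object.
#' @export
make_gene_models <- function(chrom_lengths, n_genes = 10L, seed = 1L) {
  with_seed(seed, {
    chroms <- rep(names(chrom_lengths), length.out = n_genes)
    rows <- lapply(seq_len(n_genes), function(i) {
      ch <- chroms[i]
      len <- chrom_lengths[[ch]]
      on_chr <- which(chroms[seq_len(n_genes)] == ch)
      slot <- len %/% (sum(chroms == ch) + 1)
      k <- match(i, on_chr)
      gstart <- (k - 1L) * slot + slot %/% 4
      n_ex <- sample(1:4, 1)
      ex_len <- sample(80:200, n_ex, replace = TRUE)
      gaps <- if (n_ex > 1) sample(100:400, n_ex - 1, replace = TRUE) else integer(0)
      starts <- gstart + c(0L, cumsum(ex_len[-n_ex] + gaps))
      ends <- starts + ex_len
      strand <- sample(c("+", "-"), 1)
      gid <- sprintf("gene%02d", i)
      exons <- tibble(chrom = ch, start = starts, end = ends,
                      strand = strand, gene_id = gid)
      # CDS: trim 30 bp UTR off each end of the transcript
      u <- 30L
      utr5 <- tibble(chrom = ch, start = starts[1], end = starts[1] + u,
                     strand = strand, gene_id = gid)
      utr3 <- tibble(chrom = ch, start = ends[n_ex] - u, end = ends[n_ex],
                     strand = strand, gene_id = gid)
      if (strand == "-") { tmp <- utr5; utr5 <- utr3; utr3 <- tmp }
      cds <- exons
      cds$start[1] <- cds$start[1] + u
      cds$end[n_ex] <- cds$end[n_ex] - u
      list(gene = tibble(chrom = ch, start = starts[1], end = ends[n_ex],
                         strand = strand, gene_id = gid),
           exons = exons, cds = cds, utr5 = utr5, utr3 = utr3)
    })
    gene_features(
      genes = bind_rows(lapply(rows, `[[`, "gene")),
      exons = bind_rows(lapply(rows, `[[`, "exons")),
      cds = bind_rows(lapply(rows, `[[`, "cds")),
      utr5 = bind_rows(lapply(rows, `[[`, "utr5")),
      utr3 = bind_rows(lapply(rows, `[[`, "utr3")),
      chrom_lengths = chrom_lengths
    )
  })
}

#' Write a gene feature set as GFF3
#'
#' Minimal GFF3 writer (genes, one transcript per gene, exons, CDS, UTRs)
#' that round-trips through [read_gene_features()].
#'
#' @param features A [gene_features()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  lines <- c("##gff-version 3")
  if (!is.null(features$chrom_lengths)) {
    lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                              names(features$chrom_lengths),
                              as.integer(features$chrom_lengths)))
  }
  fmt <- function(df, type, attr) {
    if (is.null(df) || nrow(df) == 0) return(character(0))
    sprintf("%s\tsinetails\t%s\t%d\t%d\t.\t%s\t.\t%s",
            df$chrom, type, df$start + 1L, df$end, df$strand, attr)
  }
  for (i in seq_len(nrow(features$genes))) {
    g <- features$genes[i, ]
    gid <- g$gene_id; tid <- paste0(gid, ".t1")
    lines <- c(
      lines,
      fmt(g, "gene", sprintf("ID=%s", gid)),
      fmt(g, "mRNA", sprintf("ID=%s;Parent=%s", tid, gid)),
      fmt(features$exons[features$exons$gene_id == gid, ], "exon",
          sprintf("Parent=%s", tid)),
      fmt(features$cds[features$cds$gene_id == gid, ], "CDS",
          sprintf("Parent=%s", tid)),
      fmt(features$utr5[features$utr5$gene_id == gid, ], "five_prime_UTR",
          sprintf("Parent=%s", tid)),
      fmt(features$utr3[features$utr3$gene_id == gid, ], "three_prime_UTR",
          sprintf("Parent=%s", tid))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Derive a variant assembly with planted edits and its PAF alignment
#'
#' Applies non-overlapping insertion/deletion edits to a genome and emits the
#' corresponding assembly-to-reference PAF records (query = variant, target =
#' reference) with exact cigars, one record per chromosome, suitable for
#' [liftover_interval()].
#'
#' @param genome Reference genome ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @param edits Tibble: `chrom`, `pos` (0-based reference coordinate),
#'   `type` (`"ins"`/`"del"`), `seq` (inserted sequence, for `ins`),
#'   `len` (deleted length, for `del`).
#' @param name Variant assembly name prefix for query chromosome names
#'   (default `"var"`, yielding e.g. `var_chr1`).
#' @return List: `genome` (variant [Biostrings::DNAStringSet]), `paf`
#'   (tibble as from [read_paf()]).
#' @export
make_variant_assembly <- function(genome, edits = NULL, name = "var") {
  genome <- as_dnastringset(genome)
  if (is.null(edits)) {
    edits <- tibble(chrom = character(), pos = integer(),
                    type = character(), seq = character(), len = integer())
  }
  if (!"seq" %in% names(edits)) edits$seq <- NA_character_
  if (!"len" %in% names(edits)) edits$len <- NA_integer_
  var_seqs <- character(0); paf_rows <- list()
  for (ch in names(genome)) {
    ref <- as.character(genome[[ch]])
    rlen <- nchar(ref)
    e <- edits |> filter(.data$chrom == ch) |> arrange(.data$pos)
    if (nrow(e) > 1) {
      span_end <- e$pos + ifelse(e$type == "del", e$len, 0L)
      if (any(e$pos[-1] < span_end[-nrow(e)])) abort("overlapping edits")
    }
    pieces <- character(0); cig <- character(0)
    cursor <- 0L; qlen <- 0L
    for (k in seq_len(nrow(e))) {
      m <- e$pos[k] - cursor
      if (m > 0) {
        pieces <- c(pieces, substr(ref, cursor + 1, e$pos[k]))
        cig <- c(cig, sprintf("%dM", m)); qlen <- qlen + m
      }
      if (e$type[k] == "ins") {
        pieces <- c(pieces, e$seq[k])
        cig <- c(cig, sprintf("%dI", nchar(e$seq[k])))
        qlen <- qlen + nchar(e$seq[k])
        cursor <- e$pos[k]
      } else {
        cig <- c(cig, sprintf("%dD", e$len[k]))
        cursor <- e$pos[k] + e$len[k]
      }
    }
    if (cursor < rlen) {
      pieces <- c(pieces, substr(ref, cursor + 1, rlen))
      cig <- c(cig, sprintf("%dM", rlen - cursor))
      qlen <- qlen + rlen - cursor
    }
    qname <- paste0(name, "_", ch)
    var_seqs[qname] <- paste(pieces, collapse = "")
    nm <- sum(as.integer(sub("M", "", grep("M$", cig, value = TRUE))))
    paf_rows[[ch]] <- tibble(
      qname = qname, qlen = qlen, qstart = 0L, qend = qlen,
      strand = "+", tname = ch, tlen = rlen, tstart = 0L, tend = rlen,
      nmatch = nm, alnlen = max(qlen, rlen), mapq = 60L,
      cigar = paste(cig, collapse = "")
    )
  }
  list(genome = Biostrings::DNAStringSet(var_seqs), paf = bind_rows(paf_rows))
}
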