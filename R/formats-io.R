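#' Read a RepeatMasker `.out` annotation file
#'
#' Parses the classic RepeatMasker `.out` dialect: three header lines followed
#' by whitespace-separated columns (score, perc div, perc del, perc ins, query,
#' begin, end, left, strand, repeat, class/family, repeat begin, repeat end,
#' left, ID, with an optional trailing `*` overlap flag). Coordinates are
#' converted from RepeatMasker's 1-based inclusive convention to the package's
#' 0-based half-open convention, the `C` strand code is mapped to `-`, and
#' percent divergence is rescaled to a fraction `D` in `[0, 1)`.
#'
#' Parenthesised "left" columns are ignored. A malformed row raises an error
#' naming its line number; a file that is empty after the headers yields a
#' zero-row tibble.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return A tibble with one row per annotation: `element_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand` (`+`/`-`), `subfamily`,
#'   `class_family`, `D` (fractional divergence), `score`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  # Header: up to three leading lines (two column-name lines and one blank).
  is_data <- function(x) grepl("^\\s*\\d+\\s", x)
  first_data <- which(vapply(lines, is_data, logical(1)))[1]
  body_idx <- if (is.na(first_data)) integer(0) else seq(first_data, length(lines))
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 14 || length(f) > 16) {
      abort(sprintf("malformed RepeatMasker row at line %d: expected 14-16 fields, found %d",
                    i, length(f)))
    }
    score <- suppressWarnings(as.numeric(f[1]))
    div   <- suppressWarnings(as.numeric(f[2]))
    begin <- suppressWarnings(as.integer(f[6]))
    endc  <- suppressWarnings(as.integer(f[7]))
    if (anyNA(c(score, div, begin, endc))) {
      abort(sprintf("malformed RepeatMasker row at line %d: non-numeric coordinate or score", i))
    }
    if (!f[9] %in% c("+", "C", "-")) {
      abort(sprintf("malformed RepeatMasker row at line %d: bad strand '%s'", i, f[9]))
    }
    id <- f[15]
    if (is.na(id) || identical(id, "*")) id <- f[length(f)]
    tibble(
      element_id = id,
      chrom = f[5],
      start = begin - 1L,
      end = endc,
      strand = if (f[9] == "+") "+" else "-",
      subfamily = f[10],
      class_family = f[11],
      D = div / 100,
      score = score
    )
  })
  out <- if (length(rows)) bind_rows(rows) else
    tibble(element_id = character(), chrom = character(), start = integer(),
           end = integer(), strand = character(), subfamily = character(),
           class_family = character(), D = numeric(), score = numeric())
  if (any(out$D >= 1)) abort("divergence >= 100% in RepeatMasker input")
  if (any(out$start >= out$end)) abort("RepeatMasker row with begin > end")
  out
}

#' Write annotations in RepeatMasker `.out` format
#'
#' Inverse of [read_repeatmasker_out()]: 0-based half-open intervals become
#' 1-based inclusive, `-` becomes `C`, and `D` is printed as a percentage.
#' Used mainly by the synthetic-fixture generator.
#'
#' @param annotations Tibble as returned by [read_repeatmasker_out()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(annotations, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query              matching         repeat                position in repeat",
    "score   div. del. ins.  sequence  begin  end          (left)    repeat           class/family      begin   end    (left)     ID",
    ""
  )
  rows <- vapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    sprintf("%5d %6.1f  0.0  0.0  %s %8d %8d (0) %s %s %s 1 %d (0) %s",
            as.integer(a$score %||% 225), a$D * 100, a$chrom,
            a$start + 1L, a$end,
            if (a$strand == "+") "+" else "C",
            a$subfamily, a$class_family %||% "SINE/tRNA",
            a$end - a$start, a$element_id)
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that uppercases
#' soft-masked bases and trims FASTA names to their first whitespace-separated
#' token.
#'
#' @param path FASTA path (plain or bgzip).
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(g))
}

#' Write a genome FASTA
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

as_dnastringset <- function(genome) {
  if (is.character(genome)) Biostrings::DNAStringSet(toupper(genome)) else genome
}

#' Extract a strand-aware genomic sequence
#'
#' Returns the forward-strand slice for `+` intervals and the reverse
#' complement for `-` intervals, always uppercase. Coordinates are 0-based
#' half-open. Vectorised over `chrom`, `start`, `end`, `strand`.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @param chrom,start,end,strand Interval fields; `strand` in `+`/`-`.
#' @return Character vector of sequences (alphabet `A`,`C`,`G`,`T`,`N`).
#' @export
extract_sequence <- function(genome, chrom, start, end, strand = "+") {
  genome <- as_dnastringset(genome)
  n <- max(length(chrom), length(start), length(end), length(strand))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n)
  end <- rep_len(end, n); strand <- rep_len(strand, n)
  vapply(seq_len(n), function(i) {
    if (!chrom[i] %in% names(genome)) {
      abort(sprintf("unknown chromosome '%s'", chrom[i]))
    }
    len <- length(genome[[chrom[i]]])
    if (start[i] < 0 || end[i] > len || start[i] >= end[i]) {
      abort(sprintf("interval %s:%d-%d out of bounds (length %d)",
                    chrom[i], start[i], end[i], len))
    }
    s <- Biostrings::subseq(genome[[chrom[i]]], start[i] + 1L, end[i])
    if (strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
}

# tibble(chrom,start,end[,strand]) in 0-based half-open -> GRanges (1-based).
to_granges <- function(df, chrom_lengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
  if (!is.null(chrom_lengths)) {
    sl <- chrom_lengths[GenomeInfoDb::seqlevels(gr)]
    if (!anyNA(sl)) GenomeInfoDb::seqlengths(gr) <- sl
  }
  gr
}

from_granges <- function(gr, extra = NULL) {
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  out$strand[out$strand == "*"] <- "+"
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  out
}

#' Build a gene feature set with derived introns and intergenic regions
#'
#' Introns are the per-gene gaps between that gene's exons; intergenic regions
#' are the complement of gene spans within chromosome bounds. Zero-length
#' derived intervals are dropped.
#'
#' @param genes,exons,cds,utr5,utr3 Tibbles with `chrom`, `start`, `end`
#'   (0-based half-open), optional `strand`, and `gene_id` (except `genes`,
#'   where `gene_id` is required).
#' @param chrom_lengths Named integer vector of chromosome lengths, required
#'   to derive intergenic regions (chromosomes without a length are skipped).
#' @return An object of class `gene_features`: a list of tibbles `genes`,
#'   `exons`, `cds`, `utr5`, `utr3`, `introns`, `intergenic`.
#' @export
gene_features <- function(genes, exons,
                          cds = NULL, utr5 = NULL, utr3 = NULL,
                          chrom_lengths = NULL) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), gene_id = character())
  fix <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(empty)
    if (!"strand" %in% names(df)) df$strand <- "+"
    if (!"gene_id" %in% names(df)) df$gene_id <- NA_character_
    as_tibble(df[, c("chrom", "start", "end", "strand", "gene_id")])
  }
  genes <- fix(genes); exons <- fix(exons)
  cds <- fix(cds); utr5 <- fix(utr5); utr3 <- fix(utr3)

  introns <- empty
  if (nrow(exons) > 0) {
    groups <- split(exons, paste(exons$gene_id, exons$chrom, exons$strand,
                                 sep = "\r"))
    introns <- bind_rows(lapply(groups, function(d) {
      gr <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
      if (length(gr) < 2) return(NULL)
      s <- sort(IRanges::start(gr)); e <- sort(IRanges::end(gr))
      tibble(chrom = d$chrom[1],
             start = e[-length(e)],            # 1-based gap -> 0-based half-open
             end = s[-1] - 1L,
             strand = d$strand[1], gene_id = d$gene_id[1])
    }))
    if (nrow(introns)) {
      introns <- introns |> filter(.data$end > .data$start)
      rownames(introns) <- NULL
    } else introns <- empty
  }

  intergenic <- empty
  if (!is.null(chrom_lengths) && nrow(genes) > 0) {
    per_chrom <- lapply(names(chrom_lengths), function(ch) {
      len <- chrom_lengths[[ch]]
      g <- genes[genes$chrom == ch, ]
      if (nrow(g) == 0) return(tibble(chrom = ch, start = 0L, end = as.integer(len),
                                      strand = "+", gene_id = NA_character_))
      cov <- GenomicRanges::reduce(to_granges(g))
      s <- GenomicRanges::start(cov) - 1L; e <- GenomicRanges::end(cov)
      starts <- c(0L, e); ends <- c(s, as.integer(len))
      keep <- ends > starts
      tibble(chrom = ch, start = starts[keep], end = ends[keep],
             strand = "+", gene_id = NA_character_)
    })
    intergenic <- bind_rows(per_chrom)
  }

  structure(
    list(genes = genes, exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
         introns = introns, intergenic = intergenic,
         chrom_lengths = chrom_lengths),
    class = "gene_features"
  )
}

#' @export
print.gene_features <- function(x, ...) {
  cat("<gene_features>\n")
  for (nm in c("genes", "exons", "cds", "utr5", "utr3", "introns", "intergenic")) {
    cat(sprintf("  %-10s %d intervals\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Parse gene models from GFF3/GTF into a gene feature set
#'
#' Reads gene, exon, CDS and UTR records with [rtracklayer::import()] and
#' resolves each feature to a gene through the `Parent`/`gene_id` attribute
#' chain (exon -> transcript -> gene for GFF3; `gene_id` for GTF). Features
#' whose gene cannot be resolved are skipped with a warning. Introns and
#' intergenic regions are derived via [gene_features()].
#'
#' @param path GFF3 or GTF file.
#' @param chrom_lengths Optional named vector of chromosome lengths; if `NULL`,
#'   lengths from the file's sequence-region headers are used when present.
#' @return A `gene_features` object.
#' @export
read_gene_features <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type
  )
  df$strand[!df$strand %in% c("+", "-")] <- "+"

  get_attr <- function(nm) {
    if (!nm %in% names(md)) return(rep(NA_character_, length(gr)))
    v <- md[[nm]]
    if (methods::is(v, "CharacterList") || is.list(v)) {
      vapply(v, function(x) if (length(x)) as.character(x[[1]]) else NA_character_,
             character(1))
    } else as.character(v)
  }
  id <- get_attr("ID"); parent <- get_attr("Parent"); gid <- get_attr("gene_id")

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  gene_ids <- ifelse(is.na(gid[is_gene]), id[is_gene], gid[is_gene])
  tx2gene <- setNames(ifelse(is.na(parent[is_tx]), gid[is_tx], parent[is_tx]),
                      ifelse(is.na(id[is_tx]), gid[is_tx], id[is_tx]))

  resolve_gene <- function(i) {
    if (!is.na(gid[i]) && gid[i] %in% gene_ids) return(gid[i])
    p <- parent[i]
    if (!is.na(p)) {
      if (p %in% gene_ids) return(p)
      if (p %in% names(tx2gene)) return(unname(tx2gene[p]))
    }
    if (!is.na(gid[i])) return(gid[i])
    NA_character_
  }

  pick <- function(types) {
    idx <- which(type %in% types)
    if (!length(idx)) return(NULL)
    g <- vapply(idx, resolve_gene, character(1))
    drop <- is.na(g)
    if (any(drop)) {
      warn(sprintf("%d %s feature(s) without a resolvable gene were skipped",
                   sum(drop), paste(types, collapse = "/")))
    }
    out <- df[idx[!drop], c("chrom", "start", "end", "strand")]
    out$gene_id <- g[!drop]
    out
  }

  genes <- df[is_gene, c("chrom", "start", "end", "strand")]
  genes$gene_id <- gene_ids

  if (is.null(chrom_lengths)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (length(sl) && !all(is.na(sl))) chrom_lengths <- sl[!is.na(sl)]
  }

  gene_features(
    genes = genes,
    exons = pick("exon"),
    cds = pick("CDS"),
    utr5 = pick(c("five_prime_UTR", "five_prime_utr", "5UTR")),
    utr3 = pick(c("three_prime_UTR", "three_prime_utr", "3UTR")),
    chrom_lengths = chrom_lengths
  )
}

tail_table_columns <- c("element_id", "chrom", "start", "end", "strand",
                        "subfamily", "method", "tail_seq", "category",
                        "D", "K", "age_my", "age_bin")

#' Write / read the tail table (TSV)
#'
#' The tail table is the pipeline's central exchange format: one row per SINE
#' tail with the fixed header `element_id, chrom, start, end, strand,
#' subfamily, method, tail_seq, category, D, K, age_my, age_bin`
#' (`start`/`end` are the 0-based half-open genomic span of the tail).
#' Columns not yet computed are written as `NA`; the round trip is lossless,
#' including empty tail sequences. [read_tail_table()] rejects files whose
#' header does not match.
#'
#' @param records Tibble holding at least `element_id`, `chrom`, `start`,
#'   `end`, `strand`; missing optional columns are filled with `NA`.
#' @param path File path.
#' @return `write_tail_table()` returns `path` invisibly; `read_tail_table()`
#'   returns the records tibble.
#' @export
write_tail_table <- function(records, path) {
  for (cl in tail_table_columns) {
    if (!cl %in% names(records)) records[[cl]] <- NA
  }
  out <- records[, tail_table_columns]
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' @rdname write_tail_table
#' @export
read_tail_table <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  if (!identical(hdr, tail_table_columns)) {
    abort(paste0("tail table header mismatch; expected: ",
                 paste(tail_table_columns, collapse = ", ")))
  }
  readr::read_tsv(
    path, na = "",
    col_types = readr::cols(
      element_id = "c", chrom = "c", start = "i", end = "i", strand = "c",
      subfamily = "c", method = "c", tail_seq = "c", category = "c",
      D = "d", K = "d", age_my = "d", age_bin = "c"
    )
  ) |>
    mutate(tail_seq = tidyr::replace_na(.data$tail_seq, ""))
}

#' Export tail intervals as BED6
#'
#' @param records Tail tibble (`chrom`, `start`, `end`, `strand`,
#'   `element_id`; score column is written as 0).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  bed <- tibble(
    chrom = records$chrom, start = records$start, end = records$end,
    name = records$element_id, score = 0L, strand = records$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
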