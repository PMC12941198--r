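#' Cutoff-motif libraries
#'
#' A cutoff library maps SINE subfamilies to ordered lists of short motifs
#' (typically 8-20 bp) that mark the body-to-tail transition of the element.
#' The file format is plain TSV with two columns, `subfamily` and `motif`;
#' a `*` subfamily acts as a global wildcard tried after any subfamily-specific
#' motifs. `cutoff_library()` builds a library from a tibble;
#' `read_cutoff_library()` parses the TSV; `default_cutoff_library()` loads the
#' synthetic library shipped with the package (the motifs used by the
#' synthetic-fixture generator — they are not biological consensus cutoffs).
#'
#' @param motifs Tibble with columns `subfamily` and `motif` (uppercase ACGT).
#' @param fallback_length Tail length used when no motif matches (default 30).
#' @return An object of class `cutoff_library`.
#' @export
cutoff_library <- function(motifs, fallback_length = 30L) {
  stopifnot(all(c("subfamily", "motif") %in% names(motifs)),
            fallback_length >= 1)
  motifs$motif <- toupper(motifs$motif)
  if (!all(grepl("^[ACGT]+$", motifs$motif))) {
    abort("cutoff motifs must be non-empty uppercase ACGT strings")
  }
  structure(
    list(motifs = as_tibble(motifs[, c("subfamily", "motif")]),
         fallback_length = as.integer(fallback_length)),
    class = "cutoff_library"
  )
}

#' @rdname cutoff_library
#' @param path Path to a two-column TSV (`subfamily`, `motif`); lines starting
#'   with `#` are ignored.
#' @export
read_cutoff_library <- function(path, fallback_length = 30L) {
  df <- readr::read_tsv(path, comment = "#", col_types = "cc",
                        col_names = c("subfamily", "motif"))
  if (nrow(df) && identical(tolower(df$subfamily[1]), "subfamily")) df <- df[-1, ]
  cutoff_library(df, fallback_length)
}

#' @rdname cutoff_library
#' @export
default_cutoff_library <- function(fallback_length = 30L) {
  read_cutoff_library(
    system.file("extdata", "cutoff_library_synthetic.tsv", package = "sinetails"),
    fallback_length
  )
}

#' @export
print.cutoff_library <- function(x, ...) {
  cat(sprintf("<cutoff_library> %d motifs, %d subfamilies, fallback %d bp\n",
              nrow(x$motifs), length(unique(x$motifs$subfamily)),
              x$fallback_length))
  invisible(x)
}

# Ordered motif list for one subfamily: subfamily-specific first, then global.
motifs_for_subfamily <- function(library, subfamily) {
  m <- library$motifs
  c(m$motif[m$subfamily == subfamily], m$motif[m$subfamily == "*"])
}

#' Locate a cutoff motif in an element sequence
#'
#' Two hierarchical passes: pass 1 requires exact matches, pass 2 allows a
#' single substitution (Hamming distance 1; `N` mismatches every base).
#' Within a pass motifs are tried in library order and the first motif with
#' any occurrence wins; among that motif's occurrences, the one whose end lies
#' closest to the element's 3' end wins, because the cutoff abuts the tail and
#' a spurious internal copy must not truncate the body.
#'
#' @param element_seq Uppercase element sequence in element orientation.
#' @param motifs Character vector of motifs, in priority order.
#' @param max_mismatch 0 (exact only) or 1 (exact pass then 1-mismatch pass).
#' @return A list with `offset` (0-based position just past the motif, i.e.
#'   where the tail starts), `motif`, and `pass` (`"cutoff_exact"` or
#'   `"cutoff_mismatch1"`), or `NULL` when nothing matches.
#' @export
locate_cutoff <- function(element_seq, motifs, max_mismatch = 1L) {
  stopifnot(max_mismatch %in% c(0L, 1L))
  if (!length(motifs) || !nzchar(element_seq)) return(NULL)
  subject <- Biostrings::DNAString(element_seq)
  for (mm in 0:max_mismatch) {
    for (motif in motifs) {
      if (nchar(motif) > nchar(element_seq)) next
      hits <- Biostrings::matchPattern(motif, subject,
                                       max.mismatch = mm, fixed = TRUE)
      if (length(hits)) {
        return(list(
          offset = max(IRanges::end(hits)),     # 1-based end == 0-based tail start
          motif = motif,
          pass = if (mm == 0) "cutoff_exact" else "cutoff_mismatch1"
        ))
      }
    }
  }
  NULL
}

#' Map a tail offset within an element to genomic coordinates
#'
#' For `+` elements the tail occupies the right (3') genomic end of the
#' element span; for `-` elements the element is read on the reverse strand,
#' so the tail occupies the left genomic end.
#'
#' @param start,end Element genomic span (0-based half-open).
#' @param strand `+` or `-`.
#' @param offset 0-based offset of the tail start within the element
#'   (element orientation).
#' @param length Tail length in bp.
#' @return Named list with genomic `start` and `end` of the tail.
#' @export
tail_genomic_interval <- function(start, end, strand, offset, length) {
  if (offset < 0 || length < 0 || offset + length > end - start) {
    abort("tail offset + length exceeds element bounds")
  }
  if (strand == "+") {
    list(start = start + offset, end = start + offset + length)
  } else {
    list(start = end - offset - length, end = end - offset)
  }
}

#' Extract SINE tails from annotated elements
#'
#' For each annotation the element sequence is read in element orientation
#' (reverse-complemented for `-` elements), the cutoff library for its
#' subfamily is applied via [locate_cutoff()], and everything downstream of
#' the matched motif becomes the tail. Elements without a recognisable cutoff
#' receive their terminal `fallback_length` bases (the whole element if
#' shorter) as the tail, with `method = "fallback"`.
#'
#' @param annotations Annotation tibble from [read_repeatmasker_out()].
#' @param genome Genome as [Biostrings::DNAStringSet] or named character.
#' @param library A [cutoff_library()].
#' @param max_mismatch Motif-matching tolerance, 0 or 1 (default 1).
#' @return Tail tibble: `element_id`, `chrom`, `start`, `end` (tail genomic
#'   span), `strand`, `subfamily`, `D`, `method`, `tail_seq`,
#'   `element_start`, `element_end`.
#' @export
extract_tails <- function(annotations, genome, library = default_cutoff_library(),
                          max_mismatch = 1L) {
  genome <- as_dnastringset(genome)
  fallback <- library$fallback_length
  rows <- purrr::pmap(annotations, function(element_id, chrom, start, end,
                                            strand, subfamily, D = NA_real_, ...) {
    elen <- end - start
    if (elen < 1) abort(sprintf("element %s shorter than 1 bp", element_id))
    seq <- extract_sequence(genome, chrom, start, end, strand)
    hit <- locate_cutoff(seq, motifs_for_subfamily(library, subfamily),
                         max_mismatch)
    if (!is.null(hit)) {
      offset <- hit$offset
      method <- hit$pass
    } else {
      offset <- elen - min(fallback, elen)
      method <- "fallback"
    }
    tlen <- elen - offset
    gi <- tail_genomic_interval(start, end, strand, offset, tlen)
    tibble(
      element_id = element_id, chrom = chrom,
      start = gi$start, end = gi$end, strand = strand,
      subfamily = subfamily, D = D, method = method,
      tail_seq = substr(seq, offset + 1L, elen),
      element_start = start, element_end = end
    )
  })
  bind_rows(rows)
}
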