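#' Intersect tails with gene features
#'
#' A tail overlaps a feature class if they share at least 1 bp. Class
#' memberships are non-exclusive (a tail inside a coding exon counts in
#' `pcgene`, `exon` and `cds` simultaneously); the `exclusive_class` column
#' additionally assigns each tail a single label with priority
#' cds > utr5 > utr3 > exon > intron > intergenic. Tails on chromosomes
#' absent from the feature set are counted intergenic with a warning.
#'
#' @param tails Tail tibble (`chrom`, `start`, `end`; the tail interval, not
#'   the whole element, is intersected).
#' @param features A [gene_features()] object.
#' @return `tails` with logical columns `pcgene`, `exon`, `intron`, `cds`,
#'   `utr5`, `utr3`, `intergenic` and the character `exclusive_class`.
#' @export
intersect_features <- function(tails, features) {
  stopifnot(inherits(features, "gene_features"))
  known <- unique(unlist(lapply(
    features[c("genes", "exons", "cds", "utr5", "utr3")],
    function(d) d$chrom
  )))
  off <- setdiff(unique(tails$chrom), known)
  if (length(off)) {
    warn(sprintf("chromosome(s) %s absent from feature set; tails there counted intergenic",
                 paste(off, collapse = ", ")))
  }
  tgr <- to_granges(tails[, c("chrom", "start", "end")])
  hit <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(rep(FALSE, nrow(tails)))
    # disjoint seqlevel sets are expected (tails off the annotation), already
    # reported above; silence the merge chatter
    suppressWarnings(
      IRanges::overlapsAny(tgr, to_granges(df), ignore.strand = TRUE))
  }
  out <- tails |>
    mutate(
      pcgene = hit(features$genes),
      exon = hit(features$exons),
      intron = hit(features$introns),
      cds = hit(features$cds),
      utr5 = hit(features$utr5),
      utr3 = hit(features$utr3)
    ) |>
    mutate(intergenic = !.data$pcgene)
  cls <- c("cds", "utr5", "utr3", "exon", "intron", "intergenic")
  pick <- apply(as.matrix(out[, cls]), 1, function(v) cls[which(v)[1]])
  out$exclusive_class <- ifelse(is.na(pick), "intergenic", pick)
  out
}

#' Per-chromosome tail counts and densities
#'
#' @param tails Tail tibble.
#' @param chrom_lengths Named vector of chromosome lengths (bp); every
#'   chromosome carrying tails must have a length.
#' @return Tibble `chrom`, `n`, `density_per_mb` (= n / (length / 1e6));
#'   chromosomes without tails get `n = 0`.
#' @export
chromosome_density <- function(tails, chrom_lengths) {
  stopifnot(all(chrom_lengths > 0))
  missing <- setdiff(unique(tails$chrom), names(chrom_lengths))
  if (length(missing)) {
    abort(sprintf("no length for chromosome(s): %s", paste(missing, collapse = ", ")))
  }
  counts <- tails |> count(.data$chrom, name = "n")
  tibble(chrom = names(chrom_lengths),
         length = as.numeric(chrom_lengths)) |>
    left_join(counts, by = "chrom") |>
    mutate(n = tidyr::replace_na(.data$n, 0L),
           density_per_mb = .data$n / (.data$length / 1e6)) |>
    select("chrom", "n", "density_per_mb", "length")
}

#' Tail category composition per feature class
#'
#' @param assignments Output of [intersect_features()] on classified tails
#'   (must carry `category`).
#' @param exclusive Use the single `exclusive_class` label (`TRUE`) or
#'   non-exclusive class memberships (default).
#' @return Tibble `feature_class` x `category` with `n` and within-class
#'   `pct` (summing to 100 per class); empty classes are omitted.
#' @export
composition_by_feature <- function(assignments, exclusive = FALSE) {
  cls <- c("pcgene", "exon", "intron", "cds", "utr5", "utr3", "intergenic")
  long <- if (exclusive) {
    assignments |>
      mutate(feature_class = .data$exclusive_class) |>
      select("feature_class", "category")
  } else {
    assignments |>
      select(dplyr::all_of(c(cls, "category"))) |>
      tidyr::pivot_longer(dplyr::all_of(cls), names_to = "feature_class",
                          values_to = "in_class") |>
      filter(.data$in_class) |>
      select("feature_class", "category")
  }
  long |>
    count(.data$feature_class, .data$category, name = "n") |>
    group_by(.data$feature_class) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup() |>
    arrange(.data$feature_class, desc(.data$n))
}
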