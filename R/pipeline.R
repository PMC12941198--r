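#' Run the full tail scan: extraction, classification, dating, context
#'
#' Chains the pipeline stages on in-memory inputs and collects the per-tail
#' table plus the summary tables behind the published figure panels. Each
#' stage logs one structured line (record counts in / out) when
#' `verbose = TRUE`.
#'
#' @param genome Genome ([Biostrings::DNAStringSet] or named character).
#' @param annotations Annotation tibble ([read_repeatmasker_out()]).
#' @param library A [cutoff_library()].
#' @param features Optional [gene_features()] for context assignment.
#' @param classifier A [classifier_config()].
#' @param clock A [clock_params()].
#' @param strict_other When `TRUE`, tails extracted by the 30-bp fallback are
#'   forced to `"Other"` instead of being classified (the stricter reading in
#'   which only cutoff-anchored tails are trusted). Default `FALSE`.
#' @param verbose Log one line per stage (default `FALSE`).
#' @return An object of class `sinetail_scan`: list with `tails` (the
#'   classified, aged, context-annotated tail tibble) and `summaries`
#'   (see [summarize_tails()]).
#' @export
sine_tail_scan <- function(genome, annotations, library = default_cutoff_library(),
                           features = NULL,
                           classifier = classifier_config(),
                           clock = clock_params(),
                           strict_other = FALSE,
                           verbose = FALSE) {
  genome <- as_dnastringset(genome)
  log_stage <- function(stage, n_in, n_out) {
    if (verbose) message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
  }
  if (nrow(annotations) == 0) {
    tails <- tibble(element_id = character(), chrom = character(),
                    start = integer(), end = integer(), strand = character(),
                    subfamily = character(), D = numeric(), method = character(),
                    tail_seq = character(), category = character(),
                    series = character(), K = numeric(), age_my = numeric(),
                    age_bin = character(), saturated = logical())
    res <- structure(list(tails = tails,
                          summaries = list(),
                          clock = clock, classifier = classifier),
                     class = "sinetail_scan")
    return(res)
  }
  tails <- extract_tails(annotations, genome, library)
  log_stage("extract", nrow(annotations), nrow(tails))
  tails <- classify_tails(tails, classifier)
  if (strict_other) {
    tails$category[tails$method == "fallback"] <- "Other"
    tails$series <- category_series(tails$category)
  }
  log_stage("classify", nrow(tails), sum(tails$category != "Other"))
  tails <- estimate_ages(tails, clock)
  log_stage("age", nrow(tails), sum(!tails$saturated))
  if (!is.null(features)) {
    tails <- intersect_features(tails, features)
    log_stage("context", nrow(tails), nrow(tails))
  }
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  structure(
    list(tails = tails,
         summaries = summarize_tails(tails, chrom_lengths, clock),
         clock = clock, classifier = classifier),
    class = "sinetail_scan"
  )
}

#' Summary tables of a classified tail set
#'
#' Six tables mirroring the headline genome-wide summaries: category,
#' family, subfamily, age-bin, chromosome and (when context columns are
#' present) feature-class composition.
#'
#' @param tails Classified (and aged) tail tibble.
#' @param chrom_lengths Named chromosome lengths for densities (optional).
#' @param clock A [clock_params()].
#' @return Named list of tibbles: `by_category`, `by_family`,
#'   `by_subfamily`, `by_age_bin`, `by_chromosome`, `by_feature` (the last
#'   two only when computable).
#' @export
summarize_tails <- function(tails, chrom_lengths = NULL,
                            clock = clock_params()) {
  pcts <- function(df, ...) {
    df |>
      count(..., .data$category, name = "n") |>
      group_by(...) |>
      mutate(pct = 100 * .data$n / sum(.data$n)) |>
      ungroup()
  }
  family <- sub("^(SINE[A-Z]?).*$", "\\1", sub("^Ssc", "", tails$subfamily))
  out <- list(
    by_category = pcts(tails),
    by_family = pcts(mutate(tails, family = family), .data$family),
    by_subfamily = pcts(tails, .data$subfamily),
    by_age_bin = temporal_composition(tails, clock)
  )
  if (!is.null(chrom_lengths)) {
    out$by_chromosome <- chromosome_density(tails, chrom_lengths)
  }
  if ("exclusive_class" %in% names(tails)) {
    out$by_feature <- composition_by_feature(tails)
  }
  out
}

#' @export
print.sinetail_scan <- function(x, ...) {
  n <- nrow(x$tails)
  n_other <- sum(x$tails$category == "Other")
  cat(sprintf("<sinetail_scan> %d tails: %d classified (%.1f%%), %d Other (%.1f%%)\n",
              n, n - n_other, if (n) 100 * (n - n_other) / n else 0,
              n_other, if (n) 100 * n_other / n else 0))
  invisible(x)
}

#' Tidy a tail scan into its per-tail table
#'
#' @param x A `sinetail_scan` object.
#' @param ... Unused.
#' @return The per-tail tibble.
#' @method tidy sinetail_scan
#' @export
tidy.sinetail_scan <- function(x, ...) x$tails

#' One-row summary of a tail scan
#'
#' @param x A `sinetail_scan` object.
#' @param ... Unused.
#' @return One-row tibble: totals, classified/Other counts and percentages,
#'   A-rich percentage among classified tails, and mean tail length.
#' @method glance sinetail_scan
#' @export
glance.sinetail_scan <- function(x, ...) {
  t <- x$tails
  n <- nrow(t); n_other <- sum(t$category == "Other")
  n_class <- n - n_other
  tibble(
    n_tails = n,
    n_classified = n_class,
    pct_classified = if (n) 100 * n_class / n else NA_real_,
    n_other = n_other,
    pct_other = if (n) 100 * n_other / n else NA_real_,
    pct_arich = if (n_class) 100 * sum(t$category == "A-rich") / n_class else NA_real_,
    mean_tail_length = if (n) mean(nchar(t$tail_seq)) else NA_real_,
    n_saturated = if ("saturated" %in% names(t)) sum(t$saturated) else 0L
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

category_palette_order <- function() tail_categories()

#' Plot category composition
#'
#' @param tails Classified tail tibble (or a `sinetail_scan`).
#' @return A ggplot: per-category counts.
#' @export
plot_category_composition <- function(tails) {
  if (inherits(tails, "sinetail_scan")) tails <- tails$tails
  d <- count(tails, .data$category, name = "n") |>
    mutate(category = factor(.data$category, levels = category_palette_order()))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::labs(x = NULL, y = "tails") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot tail composition across age bins
#'
#' @param tails Classified, aged tail tibble (or a `sinetail_scan`).
#' @param clock A [clock_params()].
#' @return A ggplot: within-bin percentage stacked bars.
#' @export
plot_temporal_composition <- function(tails, clock = clock_params()) {
  if (inherits(tails, "sinetail_scan")) { clock <- tails$clock; tails <- tails$tails }
  d <- temporal_composition(tails, clock)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age_bin, y = .data$pct,
                                  fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "insertion age (My)", y = "% of tails in bin",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot per-chromosome tail density
#'
#' @param tails Tail tibble (or a `sinetail_scan`).
#' @param chrom_lengths Named chromosome lengths.
#' @return A ggplot: tails per Mb per chromosome.
#' @export
plot_chromosome_density <- function(tails, chrom_lengths) {
  if (inherits(tails, "sinetail_scan")) tails <- tails$tails
  d <- chromosome_density(tails, chrom_lengths)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chrom, y = .data$density_per_mb)) +
    ggplot2::geom_col(fill = "#66AA55") +
    ggplot2::labs(x = NULL, y = "tails / Mb") +
    ggplot2::theme_minimal()
}

#' Autoplot method for tail scans
#'
#' @param object A `sinetail_scan`.
#' @param ... Unused.
#' @return A ggplot (category composition).
#' @importFrom ggplot2 autoplot
#' @method autoplot sinetail_scan
#' @export
autoplot.sinetail_scan <- function(object, ...) {
  plot_category_composition(object)
}
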