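#' Classifier configuration
#'
#' All thresholds of the 16-category rule system. The defaults are calibrated
#' so that every worked example sequence of the published classification table
#' reproduces its own row label; see the methods vignette for the calibration
#' and for why two printed per-row criteria ("2 or more in a row" for 4-mers
#' and 3-mers) are not usable verbatim as defaults.
#'
#' @param arich_min_run Minimum length of the longest continuous adenine run
#'   for the A-rich category (default 5).
#' @param arich_min_coverage Minimum fraction of the tail covered by that
#'   single run (default 0.70). Set `arich_total_a = TRUE` to use total
#'   adenine content instead of the longest-run coverage.
#' @param arich_total_a Logical; alternative total-A-content reading of the
#'   70% criterion (default `FALSE`).
#' @param min_consecutive Named integer vector: minimum number of adjacent
#'   tandem copies required per motif length (`"2"`, `"3"`, `"4"`, `"5"`).
#'   Defaults: 2-mer 3, 3-mer 3, 4-mer 3, 5-mer 2.
#' @param max_run_start_frac The winning tandem run must start within this
#'   fraction of the tail, measured from its 5' (body-junction) end
#'   (default 0.5; use 1 to disable). Tail microsatellites expand outward
#'   from the junction poly(A) seed, so a repeat confined to the distal 3'
#'   end of an otherwise heterogeneous tail does not characterise the tail.
#' @param composite_min_distinct Minimum number of distinct same-series motif
#'   types for a composite call (default 2).
#' @param composite_standalone Logical; when `TRUE` (default) a motif counts
#'   towards composite diversity only through occurrences not wholly embedded
#'   in an occurrence of a longer same-series motif (every `AC` inside an
#'   `AAC` is not independent evidence of an `(AC)` component).
#' @param composite_min_coverage Minimum fraction of the tail covered by
#'   occurrences of the series' motifs for a composite call (default 0.5):
#'   a composite tail is one dominated by a same-series motif mixture.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(arich_min_run = 5L,
                              arich_min_coverage = 0.70,
                              arich_total_a = FALSE,
                              min_consecutive = c(`2` = 3L, `3` = 3L,
                                                  `4` = 3L, `5` = 2L),
                              max_run_start_frac = 0.5,
                              composite_min_distinct = 2L,
                              composite_standalone = TRUE,
                              composite_min_coverage = 0.5) {
  stopifnot(arich_min_run >= 1, arich_min_coverage > 0, arich_min_coverage <= 1,
            all(min_consecutive >= 1),
            all(c("2", "3", "4", "5") %in% names(min_consecutive)),
            composite_min_distinct >= 1,
            max_run_start_frac >= 0, max_run_start_frac <= 1,
            composite_min_coverage >= 0, composite_min_coverage <= 1)
  structure(
    list(arich_min_run = as.integer(arich_min_run),
         arich_min_coverage = arich_min_coverage,
         arich_total_a = isTRUE(arich_total_a),
         min_consecutive = vapply(min_consecutive, as.integer, integer(1)),
         max_run_start_frac = max_run_start_frac,
         composite_min_distinct = as.integer(composite_min_distinct),
         composite_standalone = isTRUE(composite_standalone),
         composite_min_coverage = composite_min_coverage),
    class = "classifier_config"
  )
}

#' @export
print.classifier_config <- function(x, ...) {
  cat("<classifier_config>\n")
  cat(sprintf("  A-rich: run >= %d covering >= %d%% (%s)\n", x$arich_min_run,
              round(100 * x$arich_min_coverage),
              if (x$arich_total_a) "total A content" else "longest-run coverage"))
  cat("  min tandem copies:",
      paste(sprintf("%s-mer %d", names(x$min_consecutive), x$min_consecutive),
            collapse = ", "), "\n")
  cat(sprintf("  run anchor <= %g of tail; composite: >= %d %stypes, coverage >= %g\n",
              x$max_run_start_frac, x$composite_min_distinct,
              if (x$composite_standalone) "standalone " else "",
              x$composite_min_coverage))
  invisible(x)
}

#' Longest continuous adenine run
#'
#' Maximal run of consecutive `A` (leftmost on ties; `N` breaks runs).
#'
#' @param seq Character vector of uppercase sequences.
#' @return Tibble with `start` (0-based; 0 when there is no A) and `length`.
#' @export
longest_polya_run <- function(seq) {
  one <- function(s) {
    if (is.na(s) || !nzchar(s)) return(c(0L, 0L))
    r <- rle(strsplit(s, "")[[1]] == "A")
    if (!any(r$values)) return(c(0L, 0L))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    a <- which(r$values)
    best <- a[which.max(r$lengths[a])]
    c(starts[best], r$lengths[best])
  }
  m <- vapply(seq, one, integer(2), USE.NAMES = FALSE)
  tibble(start = m[1, ], length = m[2, ])
}

# 0-based start positions of all (possibly overlapping) occurrences of motif.
motif_occurrences <- function(seq, motif) {
  n <- nchar(seq); L <- nchar(motif)
  if (n < L) return(integer(0))
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq), fixed = TRUE)
  IRanges::start(hits) - 1L
}

#' Maximal tandem run of a motif
#'
#' Largest number of adjacent, non-overlapping copies of `motif` anywhere in
#' `seq`, at any starting phase; leftmost maximal run on ties. `N` never
#' matches any base.
#'
#' @param seq Uppercase sequence.
#' @param motif Motif of length 2-5 (any ACGT string is accepted).
#' @return One-row tibble: `motif`, `series` (`AT`/`AC`/`AG` or `none`),
#'   `max_run`, `run_span_bp`, `run_start` (0-based; 0 when `max_run` is 0).
#' @export
max_tandem_run <- function(seq, motif) {
  L <- nchar(motif)
  occ <- motif_occurrences(seq, motif)
  series <- names(which(vapply(an_series_motifs(), function(m) motif %in% m,
                               logical(1))))
  if (!length(series)) series <- "none"
  if (!length(occ)) {
    return(tibble(motif = motif, series = series, max_run = 0L,
                  run_span_bp = 0L, run_start = 0L))
  }
  occset <- occ
  best_run <- 0L; best_start <- 0L
  for (i in occ) {
    k <- 0L; j <- i
    while (j %in% occset) { k <- k + 1L; j <- j + L }
    if (k > best_run) { best_run <- k; best_start <- i }
  }
  tibble(motif = motif, series = series, max_run = best_run,
         run_span_bp = best_run * L, run_start = best_start)
}

# All 12 AN-series motif hits for one sequence (internal, vectorised scan).
all_motif_hits <- function(seq) {
  sers <- an_series_motifs()
  bind_rows(lapply(names(sers), function(ser) {
    bind_rows(lapply(sers[[ser]], function(m) max_tandem_run(seq, m)))
  }))
}

# Distinct same-series motif types "present" in seq. With standalone = TRUE a
# shorter motif counts only via occurrences not wholly inside an occurrence of
# a longer same-series motif.
series_present_types <- function(seq, series, standalone = TRUE) {
  motifs <- an_series_motifs()[[series]]
  occs <- lapply(motifs, function(m) {
    st <- motif_occurrences(seq, m)
    if (!length(st)) return(NULL)
    cbind(st, st + nchar(m))      # [start, end) per occurrence
  })
  names(occs) <- motifs
  present <- character(0)
  for (m in motifs) {
    oc <- occs[[m]]
    if (is.null(oc)) next
    if (!standalone) { present <- c(present, m); next }
    longer <- do.call(rbind, occs[motifs[nchar(motifs) > nchar(m)]])
    if (is.null(longer)) { present <- c(present, m); next }
    embedded <- vapply(seq_len(nrow(oc)), function(i) {
      any(longer[, 1] <= oc[i, 1] & oc[i, 2] <= longer[, 2])
    }, logical(1))
    if (any(!embedded)) present <- c(present, m)
  }
  present
}

# Total bp of seq covered by any occurrence of the series' motifs.
series_coverage_bp <- function(seq, series) {
  covered <- logical(nchar(seq))
  for (m in an_series_motifs()[[series]]) {
    for (st in motif_occurrences(seq, m)) {
      covered[(st + 1):(st + nchar(m))] <- TRUE
    }
  }
  sum(covered)
}

classify_one <- function(s, config) {
  if (is.na(s) || !nzchar(s)) return("Other")
  n <- nchar(s)

  # (1) A-rich: dominant continuous adenine run.
  run <- longest_polya_run(s)
  a_cov <- if (config$arich_total_a) {
    sum(strsplit(s, "")[[1]] == "A") / n
  } else {
    run$length / n
  }
  if (run$length >= config$arich_min_run && a_cov >= config$arich_min_coverage) {
    return("A-rich")
  }

  # (2) Single dominant tandem motif.
  hits <- all_motif_hits(s)
  minc <- config$min_consecutive[as.character(nchar(hits$motif))]
  ok <- hits$max_run >= minc & hits$run_start <= n * config$max_run_start_frac
  if (any(ok)) {
    h <- hits[ok, ]
    h <- h[order(-h$run_span_bp, -nchar(h$motif), h$run_start), ]
    return(paste0("(", h$motif[1], ")n"))
  }

  # (3) Composite: a same-series motif mixture dominating the tail.
  cands <- lapply(c("AT", "AC", "AG"), function(ser) {
    types <- series_present_types(s, ser, config$composite_standalone)
    cov <- series_coverage_bp(s, ser)
    if (length(types) >= config$composite_min_distinct &&
        cov / n >= config$composite_min_coverage) {
      list(series = ser, coverage = cov)
    } else NULL
  })
  cands <- purrr::compact(cands)
  if (length(cands)) {
    covs <- vapply(cands, `[[`, numeric(1), "coverage")
    return(paste0(cands[[which.max(covs)]]$series, "-composite"))
  }

  "Other"
}

#' Classify tail sequences into structural categories
#'
#' Deterministic, total decision cascade: (1) A-rich if the longest adenine
#' run is long enough and covers enough of the tail; (2) single-motif
#' `(motif)n` for the qualifying AN-series motif with the largest tandem-run
#' span (ties: longer motif, then leftmost run); (3) series composite when at
#' least two distinct motif types of one series are present and the series
#' dominates the tail (ties between series: larger motif coverage, then AT,
#' AC, AG order); (4) `"Other"`. Empty or `NA` input maps to `"Other"`.
#'
#' @param seq Character vector of tail sequences (uppercase).
#' @param config A [classifier_config()].
#' @return Character vector of category labels (see [tail_categories()]).
#' @export
classify_tail <- function(seq, config = classifier_config()) {
  vapply(seq, classify_one, character(1), config = config, USE.NAMES = FALSE)
}

#' Classify a tail table
#'
#' Data-frame-first wrapper over [classify_tail()]: adds `category` and
#' `series` columns to a tail tibble.
#'
#' @param records Tail tibble with a `tail_seq` column.
#' @param config A [classifier_config()].
#' @return `records` with `category` and `series` columns.
#' @export
classify_tails <- function(records, config = classifier_config()) {
  records |>
    mutate(category = classify_tail(.data$tail_seq, config),
           series = category_series(.data$category))
}

#' Summary statistics of tail composition
#'
#' Per-category counts and proportions, plus diagnostics of the `"Other"`
#' fraction: mean/sd tail length, mean/sd adenine fraction, the fraction of
#' Other tails with 50-70% adenine content, and the fraction retaining any
#' sub-threshold motif tandem run (>= 2 adjacent copies).
#'
#' @param records Classified tail tibble (columns `tail_seq`, `category`).
#' @return A list with `by_category` (tibble: `category`, `n`, `proportion`)
#'   and `other_stats` (one-row tibble, all-`NA` when there are no Other
#'   tails).
#' @export
tail_composition_stats <- function(records) {
  if (nrow(records) == 0) abort("no records to summarise")
  by_cat <- records |>
    count(.data$category, name = "n") |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    arrange(desc(.data$n))

  oth <- records$tail_seq[records$category == "Other"]
  oth <- oth[!is.na(oth)]
  other_stats <- if (length(oth)) {
    lens <- nchar(oth)
    afrac <- vapply(oth, function(s) {
      if (!nzchar(s)) return(0)
      mean(strsplit(s, "")[[1]] == "A")
    }, numeric(1), USE.NAMES = FALSE)
    has_run2 <- vapply(oth, function(s) {
      any(all_motif_hits(s)$max_run >= 2)
    }, logical(1), USE.NAMES = FALSE)
    tibble(
      n = length(oth),
      mean_length = mean(lens), sd_length = stats::sd(lens),
      mean_a_fraction = mean(afrac), sd_a_fraction = stats::sd(afrac),
      frac_a_50_70 = mean(afrac >= 0.5 & afrac < 0.7),
      frac_subthreshold_repeat = mean(has_run2)
    )
  } else {
    tibble(n = 0L, mean_length = NA_real_, sd_length = NA_real_,
           mean_a_fraction = NA_real_, sd_a_fraction = NA_real_,
           frac_a_50_70 = NA_real_, frac_subthreshold_repeat = NA_real_)
  }
  list(by_category = by_cat, other_stats = other_stats)
}
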