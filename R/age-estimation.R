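#' Molecular clock parameters
#'
#' @param mu Neutral substitution rate, substitutions/site/year. Default
#'   2.3e-9 (pig neutral rate).
#' @param bin_width_my Age bin width in million years (default 5).
#' @param max_bin_my Upper bound of the binned range (default 85); older ages
#'   fall in the overflow bin `"85+"` and are excluded from composition
#'   tables. `bin_width_my` must divide `max_bin_my`.
#' @param age_formula `"k-over-2mu"` (default, age = K / (2 mu)) or
#'   `"k-over-mu"` (the common transposable-element convention age = K / mu).
#' @return An object of class `clock_params`.
#' @export
clock_params <- function(mu = 2.3e-9, bin_width_my = 5, max_bin_my = 85,
                         age_formula = c("k-over-2mu", "k-over-mu")) {
  stopifnot(mu > 0, bin_width_my > 0, max_bin_my %% bin_width_my == 0)
  structure(
    list(mu = mu, bin_width_my = bin_width_my, max_bin_my = max_bin_my,
         age_formula = match.arg(age_formula)),
    class = "clock_params"
  )
}

#' Jukes-Cantor distance from proportional divergence
#'
#' `K = -0.75 * ln(1 - 4 D / 3)`, correcting observed divergence for multiple
#' substitutions at the same site. The transformation saturates at D = 0.75;
#' such elements cannot be dated.
#'
#' @param D Numeric vector of proportional divergences in `[0, 0.75)`.
#' @return Numeric vector of distances K (substitutions/site).
#' @export
jc_distance <- function(D) {
  if (any(!is.na(D) & (D < 0 | D >= 0.75))) {
    abort("divergence saturates the Jukes-Cantor transform (D must be in [0, 0.75))")
  }
  -0.75 * log(1 - 4 * D / 3)
}

#' Absolute age from Jukes-Cantor distance
#'
#' @param K Numeric vector of distances (substitutions/site).
#' @param clock A [clock_params()].
#' @return Ages in million years.
#' @export
age_from_k <- function(K, clock = clock_params()) {
  stopifnot(all(is.na(K) | K >= 0))
  denom <- if (clock$age_formula == "k-over-2mu") 2 * clock$mu else clock$mu
  K / denom / 1e6
}

#' Bin ages into fixed-width intervals
#'
#' Half-open bins `[L, L + width)` labelled `"L-U"`; ages at or beyond
#' `max_bin_my` get the overflow label (e.g. `"85+"`).
#'
#' @param age_my Numeric vector of ages (million years).
#' @param clock A [clock_params()].
#' @return Character vector of bin labels.
#' @export
bin_age <- function(age_my, clock = clock_params()) {
  if (any(!is.na(age_my) & age_my < 0)) abort("negative age")
  w <- clock$bin_width_my
  lo <- w * floor(age_my / w)
  lab <- sprintf("%g-%g", lo, lo + w)
  lab[!is.na(age_my) & age_my >= clock$max_bin_my] <-
    sprintf("%g+", clock$max_bin_my)
  lab[is.na(age_my)] <- NA_character_
  lab
}

#' Ordered levels of the age bins of a clock
#'
#' @param clock A [clock_params()].
#' @return Character vector of bin labels from youngest to the overflow bin.
#' @export
age_bin_levels <- function(clock = clock_params()) {
  lo <- seq(0, clock$max_bin_my - clock$bin_width_my, by = clock$bin_width_my)
  c(sprintf("%g-%g", lo, lo + clock$bin_width_my), sprintf("%g+", clock$max_bin_my))
}

#' Add insertion-age estimates to a tail table
#'
#' Converts each element's RepeatMasker divergence `D` to a Jukes-Cantor
#' distance `K`, an absolute age and a bin label. Elements whose divergence
#' saturates the transform (D >= 0.75) are flagged in the `saturated` column
#' and carry `NA` ages; they are excluded from downstream composition tables.
#'
#' @param records Tail tibble with a `D` column.
#' @param clock A [clock_params()].
#' @return `records` with `K`, `age_my`, `age_bin` and `saturated` columns.
#' @export
estimate_ages <- function(records, clock = clock_params()) {
  saturated <- !is.na(records$D) & records$D >= 0.75
  K <- rep(NA_real_, nrow(records))
  ok <- !is.na(records$D) & !saturated
  K[ok] <- jc_distance(records$D[ok])
  records |>
    mutate(K = K,
           age_my = age_from_k(K, clock),
           age_bin = bin_age(.data$age_my, clock),
           saturated = saturated)
}

#' Tail category composition per age bin
#'
#' @param records Classified, aged tail tibble (`category`, `age_bin`).
#' @param clock A [clock_params()]; overflow-bin records are dropped.
#' @return Tibble `age_bin` x `category` with counts `n` and within-bin
#'   percentages `pct` (summing to 100 per bin); empty bins are omitted.
#' @export
temporal_composition <- function(records, clock = clock_params()) {
  overflow <- sprintf("%g+", clock$max_bin_my)
  records |>
    filter(!is.na(.data$age_bin), .data$age_bin != overflow) |>
    count(.data$age_bin, .data$category, name = "n") |>
    group_by(.data$age_bin) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(age_bin = factor(.data$age_bin, levels = age_bin_levels(clock))) |>
    arrange(.data$age_bin, desc(.data$n))
}
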