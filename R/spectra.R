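#' Construct an IR mode table
#'
#' A validated table of vibrational modes: non-negative frequencies sorted
#' ascending and non-negative absorbance strengths epsilon in M^-1 cm^-1. A
#' structure with imaginary frequencies is not a true minimum; the flag is
#' carried and must be `FALSE` for a valid spectrum.
#'
#' @param frequency Mode frequencies in cm^-1.
#' @param epsilon Absorbance strengths in M^-1 cm^-1.
#' @param name Molecule name.
#' @param has_imaginary Whether the underlying frequency calculation produced
#'   imaginary modes (default `FALSE`).
#' @return An `ir_spectrum` tibble (`frequency`, `epsilon`) with `name` and
#'   `has_imaginary` attributes.
#' @export
ir_spectrum <- function(frequency, epsilon, name = NA_character_,
                        has_imaginary = FALSE) {
  stopifnot(length(frequency) == length(epsilon))
  if (any(frequency < 0) || any(epsilon < 0)) {
    abort("frequencies and absorbances must be non-negative")
  }
  if (isTRUE(has_imaginary)) {
    abort("spectrum flagged with imaginary frequencies: not a valid minimum")
  }
  ord <- order(frequency)
  structure(
    tibble(frequency = frequency[ord], epsilon = epsilon[ord]),
    class = c("ir_spectrum", class(tibble())),
    name = name, has_imaginary = has_imaginary
  )
}

#' Read an IR mode table from CSV
#'
#' Expects columns `frequency_cm-1` (or `frequency`) and `epsilon_M-1cm-1`
#' (or `epsilon`).
#'
#' @param path CSV path.
#' @param name Molecule name (default: file stem).
#' @return An `ir_spectrum`.
#' @export
read_ir_table <- function(path, name = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  fcol <- intersect(c("frequency_cm-1", "frequency"), names(d))[1]
  ecol <- intersect(c("epsilon_M-1cm-1", "epsilon"), names(d))[1]
  if (is.na(fcol) || is.na(ecol)) abort("CSV needs frequency and epsilon columns")
  ir_spectrum(d[[fcol]], d[[ecol]], name = name %||% sub("\\.csv$", "", basename(path)))
}

#' Generate a synthetic IR mode table
#'
#' Uniform frequencies in `window` and uniform absorbances in `eps_range`,
#' sorted by frequency; reproducible under `seed`.
#'
#' @param n_modes Number of modes (>= 0).
#' @param window Frequency interval in cm^-1, within \[0, 4000\].
#' @param eps_range Absorbance interval in M^-1 cm^-1.
#' @param seed Optional seed.
#' @param name Molecule name.
#' @return An `ir_spectrum`.
#' @export
generate_ir_table <- function(n_modes, window = c(0, 600),
                              eps_range = c(0, 400), seed = NULL,
                              name = "synthetic") {
  stopifnot("`n_modes` must be >= 0" = n_modes >= 0)
  if (window[1] > window[2] || eps_range[1] > eps_range[2]) {
    abort("inverted interval in `window` or `eps_range`")
  }
  if (window[1] < 0 || window[2] > 4000) abort("`window` must lie within [0, 4000]")
  if (!is.null(seed)) set.seed(seed)
  ir_spectrum(
    frequency = runif(n_modes, window[1], window[2]),
    epsilon = runif(n_modes, eps_range[1], eps_range[2]),
    name = name
  )
}

#' Count significant vibrational modes
#'
#' The rigidity metric: the number of modes in the closed frequency window
#' whose absorbance strength strictly exceeds the threshold. Fewer strong
#' low-frequency modes indicate a more rigid molecule.
#'
#' @param spectrum An `ir_spectrum` (or tibble with `frequency`, `epsilon`).
#' @param eps_threshold Absorbance threshold in M^-1 cm^-1 (default 200);
#'   strictly-greater comparison.
#' @param window Closed frequency window in cm^-1 (default `c(0, 600)`).
#' @return Integer count.
#' @export
count_significant_modes <- function(spectrum, eps_threshold = 200,
                                    window = c(0, 600)) {
  stopifnot(eps_threshold >= 0, window[1] <= window[2])
  sum(spectrum$frequency >= window[1] & spectrum$frequency <= window[2] &
        spectrum$epsilon > eps_threshold)
}

#' Express absorbances as small-integer ratios
#'
#' Divides the absorbances by their minimum and searches the integer scale
#' factor k in 1..`max_scale` that minimises the total rounding error of
#' `k * epsilon/min(epsilon)`, returning the rounded integers. This
#' reproduces both common reporting styles: ratios quoted relative to the
#' weakest mode and ratios whose smallest entry is larger than one.
#'
#' @param epsilon Positive absorbance values (or an `ir_spectrum`, whose
#'   `epsilon` column is used).
#' @param max_scale Largest scale factor searched (default 12).
#' @return Integer vector of the same length as `epsilon`.
#' @examples
#' absorbance_ratios(c(6, 10, 2, 3, 2, 3) * 37.5)  # 6 10 2 3 2 3
#' @export
absorbance_ratios <- function(epsilon, max_scale = 12) {
  if (inherits(epsilon, "ir_spectrum") || is.data.frame(epsilon)) {
    epsilon <- epsilon$epsilon
  }
  if (length(epsilon) == 0) abort("no modes supplied")
  if (any(epsilon <= 0)) abort("all absorbances must be positive")
  r <- epsilon / min(epsilon)
  err <- vapply(seq_len(max_scale), function(k) sum((k * r - round(k * r))^2),
                numeric(1))
  k <- which.min(err)  # which.min takes the smallest k on ties
  as.integer(round(k * r))
}

#' Rank correlation between rigidity and insertion order
#'
#' Spearman (default) rank correlation between per-molecule significant-mode
#' counts and the rank order of insertion slowness: +1 means the most rigid
#' molecule (fewest significant low-frequency modes) inserts fastest and the
#' ordering is perfectly concordant.
#'
#' @param mode_counts Named numeric vector of significant-mode counts.
#' @param insertion_order Character vector of the same molecules ordered from
#'   fastest to slowest inserter.
#' @param method `"spearman"` (default) or `"kendall"`.
#' @return Correlation coefficient in \[-1, 1\].
#' @examples
#' rigidity_correlation(
#'   c(DOX = 6, DAU = 7, IDA = 9, EPI = 12),
#'   c("DOX", "DAU", "IDA", "EPI")
#' )  # +1
#' @export
rigidity_correlation <- function(mode_counts, insertion_order,
                                 method = c("spearman", "kendall")) {
  method <- match.arg(method)
  if (length(mode_counts) < 3) abort("need at least 3 molecules")
  if (!setequal(names(mode_counts), insertion_order) ||
      length(insertion_order) != length(mode_counts)) {
    abort(paste0(
      "molecule sets differ: counts {",
      paste(sort(names(mode_counts)), collapse = ", "), "} vs order {",
      paste(sort(insertion_order), collapse = ", "), "}"
    ))
  }
  slowness_rank <- match(names(mode_counts), insertion_order)
  cor(mode_counts, slowness_rank, method = method)
}
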