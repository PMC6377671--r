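#' Published anthracycline insertion association constants
#'
#' The reported K_in values (M^-1 s^-1) for doxorubicin (DOX), epirubicin
#' (EPI), idarubicin (IDA) and daunorubicin (DAU) in POPC and DMPC bilayers,
#' from 12 x 100 ns unbiased MD per analogue and lipid. These are inputs for
#' the comparison operations ([percent_slower()], [rank_analogues()],
#' [lipid_ratio()]), not values this package recomputes.
#'
#' @return Tibble `lipid`, `analogue`, `K_in`.
#' @export
published_kin_constants <- function() {
  tibble(
    lipid = rep(c("POPC", "DMPC"), each = 4),
    analogue = rep(c("DOX", "EPI", "IDA", "DAU"), 2),
    K_in = c(3.71e9, 2.75e9, 3.09e9, 3.42e9,
             2.00e9, 1.40e9, 1.50e9, 1.88e9)
  )
}

#' Published anthracycline gas-phase dipole moments
#'
#' DFT (gas-phase) dipole magnitudes in Debye.
#'
#' @return Named numeric vector.
#' @export
published_dipole_moments <- function() {
  c(DOX = 4.5, EPI = 7.5, IDA = 2.15, DAU = 2.83)
}

#' Published significant-mode counts and insertion order
#'
#' Number of vibrational modes with absorbance epsilon > 200 M^-1 cm^-1 in
#' the 0-600 cm^-1 window per analogue, and the insertion rank order (fastest
#' inserter first) they correlate with.
#'
#' @return List with `mode_counts` (named vector) and `insertion_order`
#'   (character).
#' @export
published_mode_counts <- function() {
  list(
    mode_counts = c(DOX = 6, DAU = 7, IDA = 9, EPI = 12),
    insertion_order = c("DOX", "DAU", "IDA", "EPI")
  )
}

#' Published significant low-frequency modes of DOX and EPI
#'
#' Frequencies (cm^-1) of the significant modes in the 0-600 cm^-1 window and
#' the reported integer ratios of their absorbances. Absolute epsilon values
#' were not reported; the `epsilon` column scales the ratio so every
#' significant mode clears the 200 M^-1 cm^-1 threshold.
#'
#' @param molecule `"DOX"` or `"EPI"`.
#' @return Tibble `frequency`, `ratio`, `epsilon`.
#' @export
published_significant_modes <- function(molecule = c("DOX", "EPI")) {
  molecule <- match.arg(molecule)
  if (molecule == "DOX") {
    freq <- c(209, 231, 333, 354, 367, 472)
    ratio <- c(6, 10, 2, 3, 2, 3)
  } else {
    freq <- c(281, 287, 292, 302, 347, 353, 368, 422, 453, 468, 489, 552)
    ratio <- c(4, 4, 3, 1, 1, 4, 3, 2, 2, 2, 3, 4)
  }
  tibble(frequency = freq, ratio = ratio, epsilon = ratio * 210)
}
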