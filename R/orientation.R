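#' Tilt angle of a molecular vector against the bilayer normal
#'
#' The vector runs from the tail centroid to the head centroid; its angle to
#' the +z axis (the bilayer normal) is `acos(v_hat . z_hat)` in degrees,
#' giving values in \[0, 180\].
#'
#' @param tail_centroid,head_centroid Length-3 coordinates (A), or n x 3
#'   matrices for a batch of frames.
#' @return Angle(s) in degrees.
#' @examples
#' angle_to_normal(c(0, 0, 0), c(0, 0, 1))  # 0
#' angle_to_normal(c(0, 0, 0), c(1, 0, 0))  # 90
#' @export
angle_to_normal <- function(tail_centroid, head_centroid) {
  tm <- rbind(tail_centroid)
  hm <- rbind(head_centroid)
  if (ncol(tm) != 3 || ncol(hm) != 3 || nrow(tm) != nrow(hm)) {
    abort("centroids must be length-3 points or matching n x 3 matrices")
  }
  v <- hm - tm
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) abort("zero-length vector: tail and head centroids coincide")
  cosang <- pmin(1, pmax(-1, v[, 3] / nrm))
  acos(cosang) * 180 / pi
}

#' Classify a tilt angle as horizontal, perpendicular or unclassified
#'
#' Horizontal (H) covers angles within `h_halfwidth` of either 0 or 180
#' degrees (the tracked vector aligned with the bilayer normal, so the group
#' it spans lies flat against the membrane plane); perpendicular (P) covers
#' angles within `p_halfwidth` of 90 degrees. Everything else is unclassified
#' (U). With halfwidths below 45 degrees the windows can never overlap.
#'
#' @param theta Angle(s) in degrees, each in \[0, 180\].
#' @param h_halfwidth,p_halfwidth Window half-widths in degrees, in (0, 45);
#'   both default to 10.
#' @return Character vector over `{"H", "P", "U"}`.
#' @examples
#' classify_angle(c(5, 90, 45, 175))  # H P U H
#' @export
classify_angle <- function(theta, h_halfwidth = 10, p_halfwidth = 10) {
  if (h_halfwidth <= 0 || h_halfwidth >= 45 || p_halfwidth <= 0 || p_halfwidth >= 45) {
    abort("halfwidths must lie in (0, 45) degrees; wider windows would overlap")
  }
  if (any(theta < 0 | theta > 180)) abort("`theta` must lie in [0, 180]")
  dplyr::case_when(
    theta <= h_halfwidth | theta >= 180 - h_halfwidth ~ "H",
    abs(theta - 90) <= p_halfwidth ~ "P",
    .default = "U"
  )
}

#' Summarise an orientation series into a preference label
#'
#' Frames are classified H/P/U with [classify_angle()]; among the classified
#' frames, the label is `H` when the H share of (H + P) reaches
#' `dominance_threshold`, `P` when it falls below `1 - dominance_threshold`,
#' and the mixed label `H/P` otherwise. Optionally only frames from the
#' insertion time onward are used, matching an analysis of the molecule's
#' pose once inside the membrane.
#'
#' @param series Tibble with columns `time_ns` and `angle_deg` (e.g. one
#'   vector's rows of a trajectory's `angles` table).
#' @param from_insertion Optional window start in ns; frames before it are
#'   dropped.
#' @param dominance_threshold Fraction of classified frames required for a
#'   single-letter label (default 0.7).
#' @param h_halfwidth,p_halfwidth Passed to [classify_angle()].
#' @return A `preference_label` list: `value` in `{"H", "P", "H/P"}`,
#'   `fraction_H`, `fraction_P`, `fraction_unclassified`, `n_frames`.
#' @export
summarize_preference <- function(series, from_insertion = NULL,
                                 dominance_threshold = 0.7,
                                 h_halfwidth = 10, p_halfwidth = 10) {
  stopifnot(all(c("time_ns", "angle_deg") %in% names(series)))
  if (!is.null(from_insertion)) {
    series <- dplyr::filter(series, .data$time_ns >= from_insertion)
  }
  if (nrow(series) == 0) abort("no frames in the analysis window")
  cls <- classify_angle(series$angle_deg, h_halfwidth, p_halfwidth)
  n <- length(cls)
  f_h <- sum(cls == "H") / n
  f_p <- sum(cls == "P") / n
  f_u <- 1 - f_h - f_p
  if (f_h + f_p == 0) {
    qs <- stats::quantile(series$angle_deg, c(0, 0.25, 0.5, 0.75, 1))
    abort(paste0(
      "no frames fall in the H or P windows; angle distribution (deg): ",
      paste(sprintf("%s=%.1f", names(qs), qs), collapse = ", ")
    ))
  }
  share_h <- f_h / (f_h + f_p)
  value <- if (share_h >= dominance_threshold) "H"
           else if (share_h <= 1 - dominance_threshold) "P"
           else "H/P"
  structure(
    list(value = value, fraction_H = f_h, fraction_P = f_p,
         fraction_unclassified = f_u, n_frames = n),
    class = "preference_label"
  )
}

#' @export
print.preference_label <- function(x, ...) {
  cat(sprintf("<preference_label> %s (H %.1f%%, P %.1f%%, U %.1f%% of %d frames)\n",
              x$value, 100 * x$fraction_H, 100 * x$fraction_P,
              100 * x$fraction_unclassified, x$n_frames))
  invisible(x)
}

#' @describeIn summarize_preference One-row tibble of the label and its
#'   fractions.
#' @param x A `preference_label`.
#' @param ... Unused.
#' @export
tidy.preference_label <- function(x, ...) {
  tibble(value = x$value, fraction_H = x$fraction_H, fraction_P = x$fraction_P,
         fraction_unclassified = x$fraction_unclassified, n_frames = x$n_frames)
}

#' Histogram of tilt angles over \[0, 180\]
#'
#' Bins are half-open `[low, high)` except the last, which is closed so 180
#' is counted.
#'
#' @param series Tibble with an `angle_deg` column, or a numeric vector of
#'   angles.
#' @param bin_width Bin width in degrees; must divide 180.
#' @return Tibble `bin_low`, `bin_high`, `count`.
#' @export
angle_histogram <- function(series, bin_width = 10) {
  angles <- if (is.numeric(series)) series else series$angle_deg
  if (180 %% bin_width != 0) abort("`bin_width` must divide 180")
  if (any(angles < 0 | angles > 180)) abort("angles must lie in [0, 180]")
  n_bins <- 180 / bin_width
  idx <- pmin(floor(angles / bin_width), n_bins - 1)  # 180 falls in the last bin
  counts <- tabulate(idx + 1, nbins = n_bins)
  tibble(
    bin_low = (seq_len(n_bins) - 1) * bin_width,
    bin_high = seq_len(n_bins) * bin_width,
    count = counts
  )
}
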