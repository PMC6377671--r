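#' Component map for a lipid species
#'
#' Maps lipid atom labels to one of the four component bins used in the
#' contact histograms: choline head, phosphate, glycerol/ester linker, and
#' hydrocarbon tail. Built-in maps cover the pseudo-atom labels produced by
#' the synthetic generator; real-topology maps can be supplied as a tibble or
#' loaded from YAML/JSON with [read_component_map()]. The shipped maps are
#' coarse approximations, not a published atom-to-bin table.
#'
#' @param lipid_name `"POPC"` or `"DMPC"` for the built-in pseudo-atom maps,
#'   or a tibble with columns `atom_label`, `component`.
#' @return A `component_map` tibble (`atom_label`, `component`) with a
#'   `bin_order` attribute giving the display order.
#' @export
component_map <- function(lipid_name = "POPC") {
  bins <- c("choline", "phosphate", "glycerol", "tail")
  if (is.data.frame(lipid_name)) {
    map <- as_tibble(lipid_name)
    if (!all(c("atom_label", "component") %in% names(map))) {
      abort("a component map needs columns `atom_label` and `component`")
    }
  } else {
    # generator pseudo-atoms are labelled by their component
    map <- tibble(
      atom_label = c("choline", "phosphate", "glycerol", "tail"),
      component = bins
    )
  }
  if (anyDuplicated(map$atom_label)) {
    abort("each atom label must map to exactly one component bin")
  }
  if (length(unique(map$component)) < 2) {
    abort("a component map needs at least two bins")
  }
  structure(map, class = c("component_map", class(map)),
            bin_order = intersect(bins, unique(map$component)) %||% unique(map$component))
}

#' Read a component map from YAML or JSON
#'
#' The file holds a mapping from atom label to component bin, either flat
#' (`label: bin`) or nested under a `map` key.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `component_map` tibble.
#' @export
read_component_map <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$map)) raw <- raw$map
  component_map(tibble(
    atom_label = names(raw),
    component = unname(unlist(raw))
  ))
}

#' Assign lipid atoms to component bins
#'
#' @param lipid_atoms Tibble of lipid atoms with a `component` or
#'   `atom_label` column holding the label to look up.
#' @param map A [component_map()].
#' @param permissive If `FALSE` (strict, default) unmapped labels raise an
#'   error listing them; if `TRUE` unmapped atoms get bin `NA` and are listed
#'   in the `unmapped` attribute.
#' @return `lipid_atoms` with a `bin` column appended.
#' @export
assign_components <- function(lipid_atoms, map, permissive = FALSE) {
  stopifnot(inherits(map, "component_map"))
  label_col <- if ("atom_label" %in% names(lipid_atoms)) "atom_label" else "component"
  if (!label_col %in% names(lipid_atoms)) {
    abort("`lipid_atoms` needs an `atom_label` or `component` column")
  }
  lookup <- setNames(map$component, map$atom_label)
  bins <- unname(lookup[lipid_atoms[[label_col]]])
  unmapped <- unique(lipid_atoms[[label_col]][is.na(bins)])
  if (length(unmapped) > 0 && !permissive) {
    abort(paste0("unmapped lipid atom label(s): ", paste(unmapped, collapse = ", "),
                 " (use `permissive = TRUE` to keep them unassigned)"))
  }
  out <- dplyr::mutate(lipid_atoms, bin = bins)
  attr(out, "unmapped") <- unmapped
  out
}

#' Count drug-lipid contacts per frame and component bin
#'
#' A contact is any (solute heavy atom, lipid heavy atom) pair whose
#' minimum-image distance is at most `cutoff`. Periodicity is applied
#' laterally (x and y) only; the membrane normal is the analysis axis and the
#' synthetic boxes are not periodic in z.
#'
#' @param traj A `mem_trajectory`.
#' @param cutoff Contact distance in A (default 4, a conventional heavy-atom
#'   contact cutoff).
#' @param window Optional `c(start, end)` time window in ns; must lie within
#'   the trajectory span.
#' @param map Optional [component_map()]; defaults to the generator's
#'   pseudo-atom map.
#' @return Tibble `frame`, `time_ns`, `bin`, `count` (all bins present for
#'   every analysed frame, zero counts included).
#' @export
count_contacts <- function(traj, cutoff = 4, window = NULL,
                           map = component_map(traj$bilayer$lipid_name %||% "POPC")) {
  stopifnot(inherits(traj, "mem_trajectory"))
  if (cutoff <= 0) abort("`cutoff` must be positive")
  frames <- traj$frames
  if (nrow(frames) == 0) abort("empty trajectory")
  if (!is.null(window)) {
    span <- range(frames$time_ns)
    if (window[1] < span[1] - 1e-9 || window[2] > span[2] + 1e-9) {
      abort("analysis `window` lies outside the trajectory span")
    }
    frames <- dplyr::filter(frames, .data$time_ns >= window[1],
                            .data$time_ns <= window[2])
  }
  lip <- assign_components(traj$lipid_atoms, map)
  bins <- attr(map, "bin_order")
  lx <- traj$box["x"]; ly <- traj$box["y"]
  bin_f <- factor(lip$bin, levels = bins)

  res <- purrr::map_dfr(seq_len(nrow(frames)), function(k) {
    i <- frames$frame[k]
    dm <- drug_atom_coords(traj, i)
    lm <- lipid_atom_coords(traj, i)
    counts <- integer(length(bins))
    for (a in seq_len(nrow(dm))) {
      dx <- lm[, 1] - dm[a, 1]
      dy <- lm[, 2] - dm[a, 2]
      if (!is.na(lx)) dx <- dx - lx * round(dx / lx)
      if (!is.na(ly)) dy <- dy - ly * round(dy / ly)
      dz <- lm[, 3] - dm[a, 3]
      hit <- (dx * dx + dy * dy + dz * dz) <= cutoff^2
      if (any(hit)) counts <- counts + tabulate(bin_f[hit], nbins = length(bins))
    }
    tibble(frame = i, time_ns = frames$time_ns[k], bin = bins, count = counts)
  })
  res
}

#' Aggregate contact counts into an occurrence histogram
#'
#' Per-bin percentage of all counted interactions:
#' `100 * sum(bin counts) / sum(all counts)`. With `normalize = FALSE` only
#' raw totals are returned. A zero-contact input yields all-zero percentages
#' and sets the `empty` attribute.
#'
#' @param counts Output of [count_contacts()].
#' @param normalize Compute percentages (default `TRUE`).
#' @param weighting `"contacts"` (default) weights by the number of contact
#'   pairs; `"frames"` counts each frame-with-any-contact once per bin.
#' @return A `contact_histogram` tibble: `bin`, `raw_count`, `percentage`,
#'   with attributes `empty`, `n_frames`.
#' @export
contact_histogram <- function(counts, normalize = TRUE,
                              weighting = c("contacts", "frames")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("bin", "count") %in% names(counts)))
  if (nrow(counts) == 0) abort("no frames in `counts`")
  if (weighting == "frames") {
    counts <- dplyr::mutate(counts, count = as.integer(.data$count > 0))
  }
  agg <- dplyr::summarise(
    dplyr::group_by(counts, bin = factor(.data$bin, levels = unique(.data$bin))),
    raw_count = sum(.data$count), .groups = "drop"
  )
  agg$bin <- as.character(agg$bin)
  total <- sum(agg$raw_count)
  agg$percentage <- if (normalize && total > 0) 100 * agg$raw_count / total else
    rep(0, nrow(agg))
  out <- structure(agg, class = c("contact_histogram", class(agg)),
                   empty = total == 0,
                   n_frames = length(unique(counts$frame)))
  out
}

#' Compare full-trajectory and early-window contact histograms
#'
#' Recomputes the contact histogram restricted to the first part of the
#' trajectory (default the first 60 ns) as a control that the full-window
#' picture is not an artefact of differing insertion times, and reports the
#' per-bin absolute percentage differences.
#'
#' @param traj A `mem_trajectory`.
#' @param cutoff Contact cutoff in A.
#' @param full_window Optional `c(start, end)` ns (default: whole trajectory).
#' @param early_ns End of the early control window in ns (default 60); the
#'   early window is `c(full_window[1], early_ns)` and must lie within
#'   `full_window`.
#' @param ... Passed to [count_contacts()].
#' @return List with `full` and `early` `contact_histogram`s and
#'   `differences` (tibble `bin`, `pct_full`, `pct_early`, `abs_diff`).
#' @export
windowed_comparison <- function(traj, cutoff = 4, full_window = NULL,
                                early_ns = 60, ...) {
  full_window <- full_window %||% range(traj$frames$time_ns)
  early_window <- c(full_window[1], min(early_ns, full_window[2]))
  if (early_window[2] > full_window[2] + 1e-9) {
    abort("early window must lie within the full window")
  }
  full <- contact_histogram(count_contacts(traj, cutoff, full_window, ...))
  early <- contact_histogram(count_contacts(traj, cutoff, early_window, ...))
  diffs <- dplyr::inner_join(
    dplyr::select(as_tibble(full), "bin", pct_full = "percentage"),
    dplyr::select(as_tibble(early), "bin", pct_early = "percentage"),
    by = "bin"
  )
  diffs$abs_diff <- abs(diffs$pct_full - diffs$pct_early)
  list(full = full, early = early, differences = diffs)
}
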