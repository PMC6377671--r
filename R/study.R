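#' Default analogue kinetic/orientation specifications
#'
#' Synthetic stand-ins for the four anthracyclines with drift speeds ordered
#' DOX > DAU > IDA > EPI, so the fastest inserter is DOX and the slowest EPI,
#' and orientation behaviour shaped like the reported preference grid: the
#' tetracyclic-ring vector held perpendicular for everyone, the amino-sugar
#' and phenyl-ring vectors of DOX alternating between horizontal and
#' perpendicular poses (its rotational freedom), and fixed poses for the
#' other analogues. Speed separations are deliberately wide so that rank
#' recovery is statistically meaningful at tens of replicates.
#'
#' @return Named list of analogue specs (`v` A/ns, `D` A^2/ns, `orientation`).
#' @export
default_analogue_specs <- function() {
  rot <- function() orientation_params(c(0, 90), concentration = 50, switching_rate = 0.5)
  fix <- function(t) orientation_params(t, concentration = 50)
  list(
    DOX = list(v = 3.6, D = 2, orientation = list(
      angle1_daunosamine = rot(), angle2_phenyl_ring_D = rot(),
      angle3_tetracyclic_ring_A = fix(90))),
    DAU = list(v = 3.0, D = 2, orientation = list(
      angle1_daunosamine = fix(0), angle2_phenyl_ring_D = fix(90),
      angle3_tetracyclic_ring_A = fix(90))),
    IDA = list(v = 2.4, D = 2, orientation = list(
      angle1_daunosamine = fix(0), angle2_phenyl_ring_D = fix(90),
      angle3_tetracyclic_ring_A = fix(90))),
    EPI = list(v = 1.8, D = 2, orientation = list(
      angle1_daunosamine = fix(180), angle2_phenyl_ring_D = fix(90),
      angle3_tetracyclic_ring_A = fix(90)))
  )
}

#' Default lipid specifications
#'
#' POPC and DMPC bilayer parameters plus a drift factor encoding the more
#' ordered, saturated DMPC bilayer as a slower approach/insertion (0.6 of the
#' POPC drift), which together with DMPC's smaller A * L_z reproduces
#' association constants about half the POPC values.
#'
#' @return Named list of lipid specs.
#' @export
default_lipid_specs <- function() {
  list(
    POPC = list(lipid_name = "POPC", drift_factor = 1),
    DMPC = list(lipid_name = "DMPC", drift_factor = 0.6)
  )
}

#' Assemble a study configuration
#'
#' Describes a full study-shaped run: analogues x lipids x replicates, the
#' trajectory length, analysis options and the base seed. The default desk
#' scale is 3 repeats of 20 ns; `paper_scale = TRUE` restores the full
#' 12 repeats of 100 ns design.
#'
#' @param analogues Named list of analogue specs (see
#'   [default_analogue_specs()]); an explicit empty `orientation = list()`
#'   marks the analogue's orientation analysis as skipped.
#' @param lipids Named list of lipid specs (see [default_lipid_specs()]).
#' @param replicates Repeats per analogue x lipid cell (default 3).
#' @param length_ns Trajectory length in ns (default 20).
#' @param seed Base seed; each cell/replicate derives its own stream from it.
#' @param frame_interval Frame spacing in ns (default 0.1).
#' @param cutoff Contact cutoff in A (default 4).
#' @param early_ns Early control window in ns (default 60; clipped to the
#'   trajectory length).
#' @param persistence Insertion persistence requirement in ns (default 0.5).
#' @param dominance Orientation dominance threshold (default 0.7).
#' @param analyses Which analyses to run, subset of
#'   `c("kinetics", "orientation", "contacts")`.
#' @param paper_scale If `TRUE`, use 12 replicates of 100 ns.
#' @return A `study_config` list.
#' @export
study_config <- function(analogues = default_analogue_specs(),
                         lipids = default_lipid_specs(),
                         replicates = 3, length_ns = 20, seed = 1,
                         frame_interval = 0.1, cutoff = 4, early_ns = 60,
                         persistence = 0.5, dominance = 0.7,
                         analyses = c("kinetics", "orientation", "contacts"),
                         paper_scale = FALSE) {
  if (paper_scale) {
    replicates <- 12
    length_ns <- 100
  }
  stopifnot(
    "`replicates` must be >= 1" = replicates >= 1,
    "`length_ns` must be > 0" = length_ns > 0,
    "analogue specs must be uniquely named" =
      length(names(analogues)) == length(analogues) && !anyDuplicated(names(analogues)),
    "lipid specs must be uniquely named" =
      length(names(lipids)) == length(lipids) && !anyDuplicated(names(lipids))
  )
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(
    list(analogues = analogues, lipids = lipids, replicates = replicates,
         length_ns = length_ns, seed = seed, frame_interval = frame_interval,
         cutoff = cutoff, early_ns = early_ns, persistence = persistence,
         dominance = dominance, analyses = analyses),
    class = "study_config"
  )
}

#' Read a study configuration from YAML
#'
#' @param path YAML file with the [study_config()] fields; analogue
#'   `orientation` entries are lists with `targets`, `concentration`,
#'   `switching_rate`.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  analogues <- purrr::map(raw$analogues, function(a) {
    orient <- if (is.null(a$orientation)) NULL else
      purrr::map(a$orientation, ~ orientation_params(
        targets = unlist(.x$targets),
        concentration = .x$concentration %||% 50,
        switching_rate = .x$switching_rate %||% 0))
    spec <- list(v = a$v, D = a$D)
    if (!is.null(orient)) spec$orientation <- orient
    spec
  })
  lipids <- raw$lipids %||% default_lipid_specs()
  args <- raw[setdiff(names(raw), c("analogues", "lipids"))]
  do.call(study_config, c(list(analogues = analogues, lipids = lipids), args))
}

#' Run the full study-shaped analysis
#'
#' For every analogue x lipid cell, simulates `replicates` trajectories,
#' detects the insertion events and aggregates them into a K_in estimate,
#' summarises the orientation preference of every tracked vector from the
#' insertion time onward, and accumulates the lipid-component contact
#' histograms over the full trajectory and the early control window. Each
#' replicate draws from its own seed derived from the base seed, so a fixed
#' seed reproduces the run exactly. Failures in one cell are logged and do
#' not abort the others.
#'
#' @param config A [study_config()].
#' @return A `study_report`: tibbles `kin` (per-cell K_in estimates),
#'   `preferences` (analogue x lipid x vector labels), `contacts` (per-cell,
#'   per-window component histograms), and a `log` of stages with wall times.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  kin_rows <- list(); pref_rows <- list(); contact_rows <- list(); log_rows <- list()
  cell_i <- 0
  n_failures <- 0

  for (lipid_label in names(config$lipids)) {
    lspec <- config$lipids[[lipid_label]]
    bil_args <- lspec[setdiff(names(lspec), "drift_factor")]
    bilayer <- do.call(build_bilayer_model, bil_args)
    A <- lateral_area(bilayer)
    L_z <- water_layer_thickness(bilayer, "one")
    drift_factor <- lspec$drift_factor %||% 1

    for (analogue in names(config$analogues)) {
      cell_i <- cell_i + 1
      aspec <- config$analogues[[analogue]]
      t0 <- proc.time()[["elapsed"]]
      cell_res <- tryCatch({
        orient <- if (is.null(aspec$orientation)) default_orientation_set()
                  else aspec$orientation
        orientation_skipped <- length(orient) == 0
        kp <- kinetic_params(
          v = aspec$v * drift_factor, D = aspec$D,
          n_replicates = config$replicates, max_time = config$length_ns,
          frame_interval = config$frame_interval
        )
        fp <- list(); prefs <- list(); contact_counts <- list()
        for (r in seq_len(config$replicates)) {
          seed_r <- config$seed + cell_i * 10000 + r
          traj <- simulate_insertion_trajectory(
            bilayer, kp,
            orientation = if (orientation_skipped) list() else orient,
            seed = seed_r
          )
          det <- detect_insertion(traj, persistence = config$persistence,
                                  replicate_id = sprintf("%s_%s_r%02d", analogue, lipid_label, r))
          fp[[r]] <- det
          if ("orientation" %in% config$analyses && !orientation_skipped && det$inserted) {
            for (vec in unique(traj$angles$vector)) {
              ser <- dplyr::filter(traj$angles, .data$vector == vec)
              pl <- summarize_preference(ser, from_insertion = det$W,
                                         dominance_threshold = config$dominance)
              prefs[[length(prefs) + 1]] <- dplyr::mutate(tidy(pl), vector = vec, replicate = r)
            }
          }
          if ("contacts" %in% config$analyses) {
            cc <- count_contacts(traj, cutoff = config$cutoff)
            contact_counts[[r]] <- cc
          }
        }
        fp <- dplyr::bind_rows(fp)
        kin_row <- if ("kinetics" %in% config$analyses) {
          est <- kin_estimate(fp, A = A, L_z = L_z, analogue = analogue,
                              lipid = lipid_label)
          tidy(est)
        } else NULL

        pref_row <- if ("orientation" %in% config$analyses) {
          if (orientation_skipped || length(prefs) == 0) {
            tibble(analogue = analogue, lipid = lipid_label,
                   vector = NA_character_, label = "skipped",
                   fraction_H = NA_real_, fraction_P = NA_real_)
          } else {
            pf <- dplyr::bind_rows(prefs)
            # pool classified-frame fractions across replicates, then label
            dplyr::summarise(
              dplyr::group_by(pf, .data$vector),
              fraction_H = mean(.data$fraction_H),
              fraction_P = mean(.data$fraction_P),
              .groups = "drop"
            ) |>
              dplyr::mutate(
                share_H = .data$fraction_H / (.data$fraction_H + .data$fraction_P),
                label = dplyr::case_when(
                  .data$share_H >= config$dominance ~ "H",
                  .data$share_H <= 1 - config$dominance ~ "P",
                  .default = "H/P"
                ),
                analogue = analogue, lipid = lipid_label
              ) |>
              dplyr::select("analogue", "lipid", "vector", "label",
                            "fraction_H", "fraction_P")
          }
        } else NULL

        contact_row <- if ("contacts" %in% config$analyses) {
          all_counts <- dplyr::bind_rows(contact_counts)
          early_end <- min(config$early_ns, config$length_ns)
          full_h <- contact_histogram(all_counts)
          early_h <- contact_histogram(
            dplyr::filter(all_counts, .data$time_ns <= early_end))
          dplyr::bind_rows(
            dplyr::mutate(as_tibble(full_h), window = "full"),
            dplyr::mutate(as_tibble(early_h), window = "early")
          ) |>
            dplyr::mutate(analogue = analogue, lipid = lipid_label) |>
            dplyr::select("analogue", "lipid", "window", "bin",
                          "raw_count", "percentage")
        } else NULL
        list(kin = kin_row, pref = pref_row, contacts = contact_row, error = NULL)
      }, error = function(e) list(kin = NULL, pref = NULL, contacts = NULL,
                                  error = conditionMessage(e)))
      elapsed <- proc.time()[["elapsed"]] - t0
      if (!is.null(cell_res$error)) n_failures <- n_failures + 1
      log_rows[[cell_i]] <- tibble(
        cell = paste(analogue, lipid_label, sep = "/"),
        replicates = config$replicates, length_ns = config$length_ns,
        status = if (is.null(cell_res$error)) "ok" else "failed",
        message = cell_res$error %||% "",
        seconds = round(elapsed, 3)
      )
      kin_rows[[cell_i]] <- cell_res$kin
      pref_rows[[cell_i]] <- cell_res$pref
      contact_rows[[cell_i]] <- cell_res$contacts
    }
  }

  structure(
    list(
      kin = dplyr::bind_rows(kin_rows),
      preferences = dplyr::bind_rows(pref_rows),
      contacts = dplyr::bind_rows(contact_rows),
      log = dplyr::bind_rows(log_rows),
      config = config,
      n_failures = n_failures
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", nrow(x$log), " cells (", x$n_failures, " failed), ",
      x$config$replicates, " replicates x ", x$config$length_ns, " ns\n", sep = "")
  if (nrow(x$kin) > 0) print(x$kin)
  invisible(x)
}

#' @describeIn run_study Per-cell K_in table of a report.
#' @param x A `study_report`.
#' @param ... Unused.
#' @export
tidy.study_report <- function(x, ...) x$kin

#' @describeIn run_study One-row run summary.
#' @export
glance.study_report <- function(x, ...) {
  tibble(
    n_cells = nrow(x$log), n_failures = x$n_failures,
    replicates = x$config$replicates, length_ns = x$config$length_ns,
    seed = x$config$seed
  )
}

format_sci <- function(x) {
  ifelse(is.na(x), "NA", {
    e <- floor(log10(abs(x)))
    sprintf("%.2f × 10^%d", x / 10^e, e)
  })
}

#' Render a study report to CSV/JSON/Markdown artifacts
#'
#' Writes a K_in table shaped one row per lipid and one column per analogue
#' (scientific notation), a preference grid (vector x analogue x lipid), the
#' long contact-histogram table, a JSON bundle of the three tables, a
#' Markdown K_in table, and the run log. Missing or failed cells render as
#' `NA`. Output is deterministic for a fixed-seed report (wall times go only
#' to the log file).
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
render_tables <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    kin_csv = file.path(out_dir, "kin_table.csv"),
    kin_md = file.path(out_dir, "kin_table.md"),
    preferences = file.path(out_dir, "preference_grid.csv"),
    contacts = file.path(out_dir, "contact_histograms.csv"),
    json = file.path(out_dir, "report.json"),
    log = file.path(out_dir, "run_log.txt")
  )

  analogues <- names(report$config$analogues)
  lipids <- names(report$config$lipids)
  kin_wide <- tibble(lipid = lipids)
  for (a in analogues) {
    vals <- purrr::map_dbl(lipids, function(l) {
      row <- dplyr::filter(report$kin, .data$analogue == a, .data$lipid == l)
      if (nrow(row) == 1) row$K_in else NA_real_
    })
    kin_wide[[a]] <- formatC(vals, format = "e", digits = 2)
    kin_wide[[a]][is.na(vals)] <- NA_character_
  }
  readr::write_csv(kin_wide, paths["kin_csv"], na = "NA")

  md <- c(
    paste0("| Lipid | ", paste(analogues, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(analogues) + 1), collapse = "|"), "|"),
    purrr::map_chr(lipids, function(l) {
      vals <- purrr::map_chr(analogues, function(a) {
        row <- dplyr::filter(report$kin, .data$analogue == a, .data$lipid == l)
        if (nrow(row) == 1) format_sci(row$K_in) else "NA"
      })
      paste0("| ", l, " | ", paste(vals, collapse = " | "), " |")
    })
  )
  writeLines(md, paths["kin_md"])

  pref <- report$preferences
  if (nrow(pref) == 0) {
    pref <- tibble(analogue = character(), lipid = character(),
                   vector = character(), label = character(),
                   fraction_H = numeric(), fraction_P = numeric())
  }
  readr::write_csv(pref, paths["preferences"], na = "NA")

  contacts <- report$contacts
  if (nrow(contacts) == 0) {
    contacts <- tibble(analogue = character(), lipid = character(),
                       window = character(), bin = character(),
                       raw_count = numeric(), percentage = numeric())
  }
  readr::write_csv(contacts, paths["contacts"], na = "NA")

  jsonlite::write_json(
    list(kin = report$kin, preferences = pref, contacts = contacts),
    paths["json"], auto_unbox = TRUE, digits = NA, na = "null"
  )
  writeLines(c(
    sprintf("study run: %d cells, %d failures, seed %s",
            nrow(report$log), report$n_failures, report$config$seed),
    utils::capture.output(as.data.frame(report$log))
  ), paths["log"])
  invisible(paths)
}
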