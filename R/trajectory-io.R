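# Component label <-> role code used in the XYZ sidecar and PDB segid field
component_role <- c(choline = "CHOL", phosphate = "PO4",
                    glycerol = "GLY", tail = "TAIL")
role_component <- setNames(names(component_role), component_role)

#' Write a trajectory as a multi-MODEL PDB file
#'
#' Solute sites come first (segment `DRUG`, chain `X`), then the static lipid
#' pseudo-atoms with the component bin in the segment field (`CHOL`, `PO4`,
#' `GLY`, `TAIL`) and the leaflet in the chain field (`U`/`L`). Box dimensions
#' go in a CRYST1 record.
#'
#' @param traj A `mem_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "mem_trajectory"))
  n_frames <- nrow(traj$frames)
  lip <- traj$lipid_atoms
  n_drug <- nrow(traj$drug_offsets)
  n_atoms <- n_drug + nrow(lip)

  xyz <- matrix(NA_real_, nrow = max(n_frames, 1), ncol = 3 * n_atoms)
  if (n_frames == 0) {
    # valid header with a single all-origin model keeps readers happy
    xyz[1, ] <- c(rep(0, 3 * n_drug),
                  as.vector(t(as.matrix(lip[, c("x", "y", "z")]))))
  } else {
    for (i in seq_len(n_frames)) {
      xyz[i, ] <- c(as.vector(t(drug_atom_coords(traj, i))),
                    as.vector(t(lipid_atom_coords(traj, i))))
    }
  }

  segid <- c(rep("DRUG", n_drug), unname(component_role[lip$component]))
  chain <- c(rep("X", n_drug), ifelse(lip$leaflet == "upper", "U", "L"))
  # residue names are 3 characters in fixed-column PDB; longer names shift
  # every following column
  lip_res <- substr(traj$bilayer$lipid_name %||% "LIP", 1, 3)
  resid <- c(rep("DRG", n_drug), rep(lip_res, nrow(lip)))
  resno <- c(rep(1L, n_drug), lip$lipid + n_drug)
  elety <- c(paste0("C", seq_len(n_drug)),
             substr(toupper(lip$component), 1, 3))

  bio3d::write.pdb(
    file = path, xyz = xyz, resno = resno, resid = resid,
    eleno = seq_len(n_atoms), elety = elety, chain = chain, segid = segid,
    print.segid = TRUE
  )
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   traj$box["x"], traj$box["y"], traj$box["z"], 90, 90, 90)
  lines <- readLines(path)
  writeLines(c(cryst, lines), path)
  invisible(path)
}

#' Read a multi-MODEL PDB trajectory
#'
#' Reads a file written by [write_trajectory_pdb()] (or any multi-MODEL PDB
#' using the same segment conventions) back into a `mem_trajectory` carrying
#' explicit per-frame solute coordinates.
#'
#' @param path PDB file path.
#' @param frame_interval Frame spacing in ns used to reconstruct time stamps
#'   (default 0.1).
#' @return A `mem_trajectory` (without generator ground-truth metadata).
#' @export
read_trajectory_pdb <- function(path, frame_interval = 0.1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  is_drug <- at$segid == "DRUG"
  n_frames <- nrow(pdb$xyz)
  times <- (seq_len(n_frames) - 1) * frame_interval

  drug_idx <- which(is_drug)
  lip_idx <- which(!is_drug)
  drug_atoms_by_frame <- lapply(seq_len(n_frames), function(i) {
    m <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)[drug_idx, , drop = FALSE]
    colnames(m) <- c("x", "y", "z")
    m
  })
  lip_m <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)[lip_idx, , drop = FALSE]
  lipid_atoms <- tibble(
    atom_id = seq_along(lip_idx),
    component = unname(role_component[at$segid[lip_idx]]),
    leaflet = ifelse(at$chain[lip_idx] == "U", "upper", "lower"),
    lipid = at$resno[lip_idx],
    x = lip_m[, 1], y = lip_m[, 2], z = lip_m[, 3]
  )
  com <- t(vapply(drug_atoms_by_frame, colMeans, numeric(3)))
  cryst <- grep("^CRYST1", readLines(path, n = 5), value = TRUE)
  box <- if (length(cryst) > 0) {
    c(x = as.numeric(substr(cryst[1], 7, 15)),
      y = as.numeric(substr(cryst[1], 16, 24)),
      z = as.numeric(substr(cryst[1], 25, 33)))
  } else c(x = NA_real_, y = NA_real_, z = NA_real_)

  structure(
    list(
      frames = tibble(frame = seq_len(n_frames), time_ns = times),
      drug_com = tibble(frame = seq_len(n_frames), time_ns = times,
                        x = com[, 1], y = com[, 2], z = com[, 3]),
      drug_atoms_by_frame = drug_atoms_by_frame,
      lipid_atoms = lipid_atoms,
      angles = tibble(frame = integer(), time_ns = numeric(),
                      vector = character(), angle_deg = numeric()),
      box = box,
      bilayer = NULL,
      meta = list(frame_interval = frame_interval, source = path)
    ),
    class = "mem_trajectory"
  )
}

#' Write a trajectory as plain XYZ plus a label sidecar
#'
#' The XYZ file holds every frame (element symbols only); the sidecar CSV maps
#' atom index to role (`drug`, `CHOL`, `PO4`, `GLY`, `TAIL`) and leaflet.
#'
#' @param traj A `mem_trajectory`.
#' @param xyz_path,labels_path Output paths.
#' @return `xyz_path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, xyz_path, labels_path) {
  stopifnot(inherits(traj, "mem_trajectory"))
  lip <- traj$lipid_atoms
  n_drug <- if (!is.null(traj$drug_offsets)) nrow(traj$drug_offsets) else nrow(traj$drug_atoms_by_frame[[1]])
  n_atoms <- n_drug + nrow(lip)
  elem <- c(rep("C", n_drug),
            c(choline = "N", phosphate = "P", glycerol = "O", tail = "C")[lip$component])

  con <- file(xyz_path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(traj$frames))) {
    coords <- rbind(drug_atom_coords(traj, i), lipid_atom_coords(traj, i))
    writeLines(c(
      as.character(n_atoms),
      sprintf("frame %d t= %.4f ns", i, traj$frames$time_ns[i]),
      sprintf("%-2s %12.5f %12.5f %12.5f", elem, coords[, 1], coords[, 2], coords[, 3])
    ), con)
  }
  labels <- tibble(
    atom_index = seq_len(n_atoms),
    role = c(rep("drug", n_drug), unname(component_role[lip$component])),
    leaflet = c(rep(NA_character_, n_drug), lip$leaflet)
  )
  readr::write_csv(labels, labels_path)
  invisible(xyz_path)
}

#' Read an XYZ trajectory with its label sidecar
#'
#' @param xyz_path,labels_path Paths written by [write_trajectory_xyz()].
#' @param frame_interval Frame spacing in ns (default 0.1).
#' @return A `mem_trajectory` with explicit per-frame solute coordinates.
#' @export
read_trajectory_xyz <- function(xyz_path, labels_path, frame_interval = 0.1) {
  labels <- readr::read_csv(labels_path, show_col_types = FALSE)
  lines <- readLines(xyz_path)
  n_atoms <- as.integer(lines[1])
  block <- n_atoms + 2
  n_frames <- length(lines) %/% block
  drug_rows <- which(labels$role == "drug")
  lip_rows <- which(labels$role != "drug")

  parse_frame <- function(i) {
    body <- lines[((i - 1) * block + 3):((i - 1) * block + 2 + n_atoms)]
    parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    m <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
    colnames(m) <- c("x", "y", "z")
    m
  }
  frames_m <- lapply(seq_len(n_frames), parse_frame)
  drug_atoms_by_frame <- lapply(frames_m, function(m) m[drug_rows, , drop = FALSE])
  lip_m <- frames_m[[1]][lip_rows, , drop = FALSE]
  times <- (seq_len(n_frames) - 1) * frame_interval
  com <- t(vapply(drug_atoms_by_frame, colMeans, numeric(3)))

  structure(
    list(
      frames = tibble(frame = seq_len(n_frames), time_ns = times),
      drug_com = tibble(frame = seq_len(n_frames), time_ns = times,
                        x = com[, 1], y = com[, 2], z = com[, 3]),
      drug_atoms_by_frame = drug_atoms_by_frame,
      lipid_atoms = tibble(
        atom_id = seq_along(lip_rows),
        component = unname(role_component[labels$role[lip_rows]]),
        leaflet = labels$leaflet[lip_rows],
        lipid = NA_integer_,
        x = lip_m[, 1], y = lip_m[, 2], z = lip_m[, 3]
      ),
      angles = tibble(frame = integer(), time_ns = numeric(),
                      vector = character(), angle_deg = numeric()),
      box = c(x = NA_real_, y = NA_real_, z = NA_real_),
      bilayer = NULL,
      meta = list(frame_interval = frame_interval, source = xyz_path)
    ),
    class = "mem_trajectory"
  )
}

#' Write the ground-truth manifest for a set of generated trajectories
#'
#' Records the generator's true parameters (drift, diffusion, travel
#' distance), each replicate's true first-crossing time, and the orientation
#' targets, as JSON — the reference against which analysis-stage estimates
#' can be validated.
#'
#' @param trajs A `mem_trajectory` or list of them.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(trajs, path) {
  if (inherits(trajs, "mem_trajectory")) trajs <- list(trajs)
  m1 <- trajs[[1]]$meta
  manifest <- list(
    v = m1$v, D = m1$D, d = m1$d, start_z = m1$start_z,
    surface_z = m1$surface_z,
    first_crossing_time = purrr::map_dbl(trajs, ~ .x$meta$first_crossing_time %||% NA_real_),
    orientation_targets = m1$orientation_targets,
    seeds = purrr::map(trajs, ~ .x$meta$seed)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
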