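#' Orientation parameters for a tracked molecular vector
#'
#' Describes how a molecular vector's tilt against the bilayer normal is
#' generated: angles concentrate around one target (or alternate between two
#' targets with a telegraph switching process, emulating a molecule that
#' rotates between horizontal and perpendicular poses).
#'
#' @param targets One or two target angles in degrees, each in \[0, 180\].
#' @param concentration Non-negative concentration of the angular
#'   distribution; 0 is isotropic, `Inf` locks the angle to the target. For
#'   finite positive values angles are drawn as target + Gaussian noise with
#'   sd `1/sqrt(concentration)` radians, reflected into \[0, 180\].
#' @param switching_rate Rate (1/ns) of alternation between the two targets;
#'   0 (default) keeps the first target throughout.
#' @return An `orientation_params` list.
#' @export
orientation_params <- function(targets, concentration = 50, switching_rate = 0) {
  stopifnot(
    "`targets` must be 1 or 2 angles" = length(targets) %in% c(1, 2),
    "target angles must lie in [0, 180]" = all(targets >= 0 & targets <= 180),
    "`concentration` must be >= 0" = length(concentration) == 1 && concentration >= 0,
    "`switching_rate` must be >= 0" = switching_rate >= 0
  )
  if (switching_rate > 0 && length(targets) != 2) {
    abort("switching requires two target angles")
  }
  structure(
    list(targets = targets, concentration = concentration,
         switching_rate = switching_rate),
    class = "orientation_params"
  )
}

#' Default tracked-vector orientation set
#'
#' Three tracked molecular vectors: the amino-sugar (daunosamine) arm
#' alternating between horizontal and perpendicular poses, the distal phenyl
#' ring axis, and the long axis of the fused tetracyclic ring system, the
#' last two held near 90 degrees.
#'
#' @return Named list of [orientation_params()].
#' @export
default_orientation_set <- function() {
  list(
    angle1_daunosamine = orientation_params(c(0, 90), concentration = 50, switching_rate = 0.5),
    angle2_phenyl_ring_D = orientation_params(90, concentration = 50),
    angle3_tetracyclic_ring_A = orientation_params(90, concentration = 50)
  )
}

# draw one angle series (degrees) for a vector
sample_angle_series <- function(op, times) {
  n <- length(times)
  if (n == 0) return(numeric(0))
  if (op$switching_rate > 0) {
    dt <- if (n > 1) diff(times[1:2]) else 0
    p_switch <- 1 - exp(-op$switching_rate * dt)
    flips <- runif(n) < p_switch
    state <- 1 + (cumsum(flips) %% 2)
  } else {
    state <- rep(1L, n)
  }
  target <- op$targets[state]
  if (is.infinite(op$concentration)) return(target)
  if (op$concentration == 0) return(acos(runif(n, -1, 1)) * 180 / pi)
  sd_deg <- (180 / pi) / sqrt(op$concentration)
  theta <- target + rnorm(n, 0, sd_deg)
  # reflect into [0, 180]
  theta <- abs(theta)
  theta <- ifelse(theta > 180, 360 - theta, theta)
  theta
}

#' Simulate a synthetic membrane-insertion trajectory
#'
#' Generates one replicate of the study geometry: a solute starts in the
#' water phase above the bilayer (by default 29 A above the bilayer center),
#' its center-of-mass depth follows an Euler-Maruyama drift-diffusion path
#' (drift `v` toward the membrane, diffusion `D`), reflecting at the far
#' water boundary. After the first crossing below the proximal phosphate
#' plane the depth relaxes (Ornstein-Uhlenbeck) toward a settle depth, or
#' follows an explicit `depth_schedule`. Lipid pseudo-atoms are placed from
#' the bilayer's component z-profiles and carry frame-to-frame thermal
#' motion (z redrawn from the profiles, lateral jitter) so contact statistics
#' sample the component distributions rather than one frozen configuration;
#' per-frame tilt angles of the tracked molecular vectors are drawn from
#' their [orientation_params()].
#'
#' @param bilayer A [build_bilayer_model()] object.
#' @param kinetics A [kinetic_params()] object. The travel distance is
#'   `kinetics$d` if set, else `start_above_center - phosphate_plane_upper`.
#' @param orientation Named list of [orientation_params()], one per tracked
#'   vector (default [default_orientation_set()] definitions).
#' @param seed Seed overriding `kinetics$seed`.
#' @param n_drug_atoms Number of solute heavy-atom pseudo-sites rigidly
#'   attached to the center of mass (default 5).
#' @param atoms_per_component Lipid pseudo-atoms per component per lipid:
#'   a single count or a named vector per component. The default mirrors the
#'   heavy-atom counts of a phosphatidylcholine lipid (choline 5, phosphate 4,
#'   glycerol/ester 6, tail 14) so contact statistics weight the components
#'   the way per-atom contact counting on a real topology would.
#' @param settle_depth Post-insertion target depth in A (default: 3 A below
#'   the proximal phosphate plane).
#' @param depth_schedule Optional tibble (`time_ns`, `target_z`) giving a
#'   stepwise post-insertion target depth; overrides `settle_depth`.
#' @param n_frames Override the frame count (`max_time/frame_interval` steps
#'   plus the t = 0 frame by default); 0 gives an empty trajectory with a
#'   valid header.
#'
#' @return A `mem_trajectory` object: frames, center-of-mass path, rigid
#'   solute site offsets, lipid pseudo-atoms, per-frame vector angles, box
#'   dimensions, and ground-truth metadata (`meta$first_crossing_time` is the
#'   first frame time at or below the phosphate plane, NA if never reached).
#' @export
simulate_insertion_trajectory <- function(bilayer, kinetics,
                                          orientation = default_orientation_set(),
                                          seed = NULL,
                                          n_drug_atoms = 5,
                                          atoms_per_component = c(
                                            choline = 5, phosphate = 4,
                                            glycerol = 6, tail = 14),
                                          settle_depth = NULL,
                                          depth_schedule = NULL,
                                          n_frames = NULL) {
  stopifnot(inherits(bilayer, "bilayer_model"), inherits(kinetics, "kinetic_params"))
  dt <- kinetics$frame_interval
  if (dt <= 0) abort("`frame_interval` must be positive")
  seed <- seed %||% kinetics$seed
  if (!is.null(seed)) set.seed(seed)

  plane <- bilayer$phosphate_plane_upper
  d <- kinetics$d %||% (kinetics$start_above_center - plane)
  if (is.null(d) || d <= 0) {
    abort("start height must be above the proximal phosphate plane (d > 0)")
  }
  z0 <- plane + d
  top <- bilayer$box_z / 2
  bottom <- -bilayer$box_z / 2
  if (z0 > top) abort("start height lies outside the box")
  settle_depth <- settle_depth %||% (plane - 3)

  n_steps <- round(kinetics$max_time / dt)
  n_frames <- n_frames %||% (n_steps + 1)
  times <- if (n_frames > 0) (seq_len(n_frames) - 1) * dt else numeric(0)

  # center-of-mass path
  v <- kinetics$v; D <- kinetics$D
  z <- numeric(n_frames)
  x <- numeric(n_frames)
  y <- numeric(n_frames)
  inserted_at <- NA_real_
  if (n_frames > 0) {
    z[1] <- z0
    x[1] <- runif(1, 0, bilayer$box_x)
    y[1] <- runif(1, 0, bilayer$box_y)
    noise <- rnorm(max(n_frames - 1, 0))
    lat_noise_x <- rnorm(max(n_frames - 1, 0))
    lat_noise_y <- rnorm(max(n_frames - 1, 0))
    sig <- sqrt(2 * D * dt)
    inside <- z[1] <= plane
    if (inside) inserted_at <- times[1]
    k_relax <- 1 # 1/ns relaxation after insertion
    for (i in seq_len(n_frames - 1)) {
      if (!inside) {
        znew <- z[i] - v * dt + sig * noise[i]
        if (znew > top) znew <- 2 * top - znew
      } else {
        target <- depth_target(depth_schedule, times[i + 1], settle_depth)
        znew <- z[i] - k_relax * (z[i] - target) * dt +
          sqrt(2 * max(D, 1e-6) / 2 * dt) * noise[i]
        if (znew < bottom) znew <- 2 * bottom - znew
        if (znew > top) znew <- 2 * top - znew
      }
      z[i + 1] <- znew
      x[i + 1] <- (x[i] + sig * lat_noise_x[i]) %% bilayer$box_x
      y[i + 1] <- (y[i] + sig * lat_noise_y[i]) %% bilayer$box_y
      if (!inside && znew <= plane) {
        inside <- TRUE
        inserted_at <- times[i + 1]
      }
    }
  }

  # rigid solute pseudo-sites: fixed offsets around the center of mass
  offs <- matrix(rnorm(n_drug_atoms * 3), ncol = 3)
  offs <- offs / sqrt(rowSums(offs^2)) * runif(n_drug_atoms, 0.5, 2)
  offs <- sweep(offs, 2, colMeans(offs))
  colnames(offs) <- c("dx", "dy", "dz")

  lipid_atoms <- place_lipid_atoms(bilayer, atoms_per_component)

  angles <- purrr::imap_dfr(orientation, function(op, nm) {
    tibble(
      frame = seq_len(n_frames), time_ns = times,
      vector = nm, angle_deg = sample_angle_series(op, times)
    )
  })
  if (nrow(angles) == 0) {
    angles <- tibble(frame = integer(), time_ns = numeric(),
                     vector = character(), angle_deg = numeric())
  }

  structure(
    list(
      frames = tibble(frame = seq_len(n_frames), time_ns = times),
      drug_com = tibble(frame = seq_len(n_frames), time_ns = times, x = x, y = y, z = z),
      drug_offsets = offs,
      lipid_atoms = lipid_atoms,
      angles = angles,
      box = c(x = bilayer$box_x, y = bilayer$box_y, z = bilayer$box_z),
      bilayer = bilayer,
      meta = list(
        v = v, D = D, d = d, start_z = z0, surface_z = plane,
        settle_depth = settle_depth,
        first_crossing_time = inserted_at,
        frame_interval = dt,
        lipid_motion = TRUE,
        orientation_targets = purrr::map(orientation, "targets"),
        seed = seed
      )
    ),
    class = "mem_trajectory"
  )
}

depth_target <- function(depth_schedule, t, settle_depth) {
  if (is.null(depth_schedule)) return(settle_depth)
  idx <- which(depth_schedule$time_ns <= t)
  if (length(idx) == 0) settle_depth else depth_schedule$target_z[max(idx)]
}

# lipid pseudo-atoms from the component z-profiles, both leaflets;
# atoms_per_component may be a single count or a named per-component vector
place_lipid_atoms <- function(bilayer, atoms_per_component = 1) {
  prof <- bilayer$component_profiles
  n_at <- if (is.null(names(atoms_per_component))) {
    rep(atoms_per_component[1], nrow(prof))
  } else {
    out <- atoms_per_component[prof$component]
    out[is.na(out)] <- 1
    unname(out)
  }
  prof <- prof[rep(seq_len(nrow(prof)), n_at), ]
  per_leaflet <- tidyr::expand_grid(
    lipid = seq_len(bilayer$n_per_leaflet),
    prof
  )
  atoms <- dplyr::bind_rows(
    dplyr::mutate(per_leaflet, leaflet = "upper"),
    dplyr::mutate(per_leaflet, leaflet = "lower")
  )
  n <- nrow(atoms)
  atoms <- dplyr::mutate(
    atoms,
    mean_z = ifelse(.data$leaflet == "upper", .data$mean_z, -.data$mean_z),
    x = runif(n, 0, bilayer$box_x),
    y = runif(n, 0, bilayer$box_y),
    z = rnorm(n, mean = .data$mean_z, sd = .data$sd_z),
    atom_id = dplyr::row_number()
  )
  dplyr::select(atoms, "atom_id", "component", "leaflet", "lipid",
                "x", "y", "z", "mean_z", "sd_z")
}

# lipid pseudo-atom coordinates at a frame. The generator's lipids are a
# mean-field representation of the component densities (uniform laterally,
# Gaussian z-profile per component), so each frame after the first is an
# independent draw from that density — standing in for lipid conformational
# fluctuation and lateral diffusion, which are fast on the 100 ns scale.
# Frame 1 is the stored placement. The resampling stream is derived from the
# trajectory seed and the frame index, so it is reproducible and leaves the
# caller's RNG state untouched. Toy or imported trajectories (no profile
# columns) are static.
lipid_atom_coords <- function(traj, frame_idx) {
  lip <- traj$lipid_atoms
  base <- as.matrix(lip[, c("x", "y", "z")])
  if (!isTRUE(traj$meta$lipid_motion) || frame_idx == 1 ||
      !all(c("mean_z", "sd_z") %in% names(lip))) {
    return(base)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(abs((traj$meta$seed %||% 0) * 131L + frame_idx) %% .Machine$integer.max)
  n <- nrow(lip)
  cbind(
    x = runif(n, 0, traj$box[["x"]]),
    y = runif(n, 0, traj$box[["y"]]),
    z = rnorm(n, mean = lip$mean_z, sd = lip$sd_z)
  )
}

#' @export
print.mem_trajectory <- function(x, ...) {
  cat("<mem_trajectory> ", nrow(x$frames), " frames, ",
      nrow(x$drug_offsets %||% matrix(nrow = 0, ncol = 3)), " solute sites, ",
      nrow(x$lipid_atoms), " lipid pseudo-atoms\n", sep = "")
  fc <- x$meta$first_crossing_time
  cat("  first crossing below phosphate plane: ",
      if (is.na(fc)) "never" else paste0(fc, " ns"), "\n", sep = "")
  invisible(x)
}

#' Solute depth series of a trajectory
#'
#' @param traj A `mem_trajectory`.
#' @return Tibble with `frame`, `time_ns`, `z` (A, bilayer center at 0).
#' @export
drug_depth <- function(traj) {
  stopifnot(inherits(traj, "mem_trajectory"))
  dplyr::select(traj$drug_com, "frame", "time_ns", "z")
}

# coordinates of solute sites at the given frame index (matrix n x 3);
# works both for generated (com + rigid offsets) and imported
# (explicit per-frame atoms) trajectories
drug_atom_coords <- function(traj, frame_idx) {
  if (!is.null(traj$drug_atoms_by_frame)) {
    m <- traj$drug_atoms_by_frame[[frame_idx]]
    return(m)
  }
  com <- traj$drug_com[frame_idx, ]
  sweep(traj$drug_offsets, 2, -c(com$x, com$y, com$z))
}
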