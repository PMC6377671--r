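# Minimal hand-built trajectory: a single-site solute following a given z
# series over lipid atoms supplied as a tibble. Used to exercise the analysis
# operations on exactly known geometry.
make_toy_traj <- function(z, dt = 0.1,
                          lipid_atoms = NULL,
                          box = c(x = 20, y = 20, z = 80),
                          surface_z = NULL,
                          drug_xy = c(10, 10),
                          drug_offsets = matrix(0, nrow = 1, ncol = 3)) {
  n <- length(z)
  times <- (seq_len(n) - 1) * dt
  if (is.null(lipid_atoms)) {
    lipid_atoms <- tibble::tibble(
      atom_id = 1L, component = "phosphate", leaflet = "upper",
      lipid = 1L, x = 10, y = 10, z = 18.5
    )
  }
  colnames(drug_offsets) <- c("dx", "dy", "dz")
  structure(
    list(
      frames = tibble::tibble(frame = seq_len(n), time_ns = times),
      drug_com = tibble::tibble(frame = seq_len(n), time_ns = times,
                                x = drug_xy[1], y = drug_xy[2], z = z),
      drug_offsets = drug_offsets,
      lipid_atoms = lipid_atoms,
      angles = tibble::tibble(frame = integer(), time_ns = numeric(),
                              vector = character(), angle_deg = numeric()),
      box = box,
      bilayer = NULL,
      meta = list(surface_z = surface_z, frame_interval = dt)
    ),
    class = "mem_trajectory"
  )
}

# molecule_structure from plain vectors
make_structure <- function(label, element, x, y, z, charge = NA_real_) {
  s <- tibble::tibble(label = label, element = element,
                      x = x, y = y, z = z, charge = charge)
  structure(s, class = c("molecule_structure", class(s)), name = "toy")
}

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
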