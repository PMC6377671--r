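#' Read a molecular structure from a PDB file
#'
#' Parses ATOM/HETATM records; element symbols are taken from the element
#' columns when present, otherwise inferred from the leading letters of the
#' atom-name field. Partial charges (in units of e) may be joined from a
#' sidecar CSV with columns `atom_label`, `charge_e`.
#'
#' @param pdb_file Path to a PDB file.
#' @param charges_csv Optional sidecar CSV path.
#' @param name Molecule name (default: file stem).
#' @return A `molecule_structure`: tibble `label`, `element`, `x`, `y`, `z`,
#'   `charge` with a `name` attribute.
#' @export
read_structure <- function(pdb_file, charges_csv = NULL, name = NULL) {
  pdb <- bio3d::read.pdb(pdb_file)
  at <- pdb$atom
  if (anyDuplicated(at$elety)) {
    dups <- unique(at$elety[duplicated(at$elety)])
    abort(paste0("duplicate atom labels in ", pdb_file, ": ",
                 paste(dups, collapse = ", ")))
  }
  element <- at$elesy
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    element[missing_el] <- infer_element(at$elety[missing_el])
  }
  atoms <- tibble(
    label = at$elety, element = element,
    x = at$x, y = at$y, z = at$z,
    charge = NA_real_
  )
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite coordinates in structure")
  }
  if (!is.null(charges_csv)) {
    ch <- readr::read_csv(charges_csv, show_col_types = FALSE)
    stopifnot(all(c("atom_label", "charge_e") %in% names(ch)))
    atoms$charge <- ch$charge_e[match(atoms$label, ch$atom_label)]
    qs <- sum(atoms$charge, na.rm = TRUE)
    if (all(!is.na(atoms$charge)) && abs(qs - round(qs)) > 1e-3) {
      warn(sprintf("total charge %.4f e is not within 1e-3 of an integer", qs))
    }
  }
  structure(atoms, class = c("molecule_structure", class(atoms)),
            name = name %||% sub("\\.pdb$", "", basename(pdb_file)))
}

# element from the leading letters of an atom name, e.g. "CA1" -> "C".
# Two-letter elements are honoured only for the halogens that cannot be
# confused with organic naming conventions ("CA1" is an alpha carbon, not
# calcium, in a drug structure).
infer_element <- function(elety) {
  lead <- toupper(sub("[^A-Za-z].*$", "", elety))
  two <- substr(lead, 1, 2)
  one <- substr(lead, 1, 1)
  ifelse(two %in% c("CL", "BR"), two, one)
}

#' Write a molecule structure to PDB
#'
#' @param structure A `molecule_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "molecule_structure"))
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(structure[, c("x", "y", "z")]))),
    resno = rep(1L, nrow(structure)), resid = rep("LIG", nrow(structure)),
    eleno = seq_len(nrow(structure)), elety = structure$label,
    elesy = structure$element, chain = rep("A", nrow(structure))
  )
  invisible(path)
}

#' Point-charge dipole moment
#'
#' mu = sum(q_i r_i), converted at 1 e.A = 4.80321 Debye. For a net-neutral
#' molecule the dipole is origin-independent; for a net-charged species it is
#' computed about the center of nominal mass and a warning flags the
#' origin dependence.
#'
#' @param structure A `molecule_structure` with charges on every atom.
#' @return List: `magnitude` (Debye), `direction` (unit vector, `NA` with
#'   `direction_defined = FALSE` for a vanishing dipole), `net_charge` (e),
#'   `origin` used.
#' @examples
#' s <- tibble::tibble(
#'   label = c("A", "B"), element = c("C", "C"),
#'   x = c(0, 1), y = 0, z = 0, charge = c(0.2082, -0.2082)
#' )
#' class(s) <- c("molecule_structure", class(s))
#' dipole_moment(s)$magnitude  # ~1 Debye
#' @export
dipole_moment <- function(structure) {
  stopifnot(inherits(structure, "molecule_structure"))
  if (any(is.na(structure$charge))) {
    abort(paste0("atoms without charges: ",
                 paste(structure$label[is.na(structure$charge)], collapse = ", ")))
  }
  q <- structure$charge
  r <- as.matrix(structure[, c("x", "y", "z")])
  net <- sum(q)
  origin <- c(0, 0, 0)
  if (abs(net) > 1e-3) {
    m <- nominal_mass(structure$element)
    origin <- colSums(r * m) / sum(m)
    warn(sprintf(
      "net charge %.3f e: dipole is origin-dependent; using center of nominal mass",
      net))
  }
  rc <- sweep(r, 2, origin)
  mu <- unname(colSums(rc * q)) * DEBYE_PER_E_ANGSTROM
  mag <- sqrt(sum(mu^2))
  if (mag < 1e-12) {
    list(magnitude = 0, direction = c(NA_real_, NA_real_, NA_real_),
         direction_defined = FALSE, net_charge = net, origin = origin)
  } else {
    list(magnitude = mag, direction = mu / mag, direction_defined = TRUE,
         net_charge = net, origin = origin)
  }
}

nominal_mass <- function(element) {
  masses <- c(H = 1, C = 12, N = 14, O = 16, P = 31, S = 32, CL = 35, BR = 80,
              F = 19, NA. = 23, MG = 24, K = 39, CA = 40, FE = 56, ZN = 65)
  m <- masses[toupper(element)]
  m[is.na(m)] <- 12
  unname(m)
}

#' Intramolecular hydrogen-bond distance
#'
#' Euclidean distance between a named donor hydrogen and a named acceptor
#' heavy atom.
#'
#' @param structure A `molecule_structure`.
#' @param donor_h_label,acceptor_label Atom labels.
#' @return Distance in A.
#' @export
hbond_distance <- function(structure, donor_h_label, acceptor_label) {
  stopifnot(inherits(structure, "molecule_structure"))
  pick <- function(lab) {
    i <- which(structure$label == lab)
    if (length(i) != 1) abort(paste0("atom label not found (or not unique): ", lab))
    as.numeric(structure[i, c("x", "y", "z")])
  }
  h <- pick(donor_h_label)
  a <- pick(acceptor_label)
  sqrt(sum((h - a)^2))
}
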