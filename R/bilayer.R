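#' Build a symmetric bilayer model
#'
#' Constructs the geometric description of a symmetric phosphatidylcholine
#' bilayer used by the synthetic trajectory generator and the kinetics
#' analysis: lateral area, phosphate planes, water-slab thickness derived from
#' the hydration level, and per-component Gaussian z-profiles used to place
#' lipid pseudo-atoms. The bilayer center sits at z = 0 and the membrane
#' normal is the z axis.
#'
#' Built-in component profiles are provided for POPC and DMPC. The water slab
#' thickness is derived from the hydration level assuming a per-water volume
#' of 30 A^3 (bulk liquid water), spread over the two leaflet-facing slabs.
#'
#' @param lipid_name Lipid species, `"POPC"` or `"DMPC"` (any other name
#'   requires an explicit `component_profiles` table).
#' @param area_per_lipid Lateral area per lipid in A^2. Defaults: POPC 65,
#'   DMPC 60.
#' @param thickness Phosphate-to-phosphate bilayer thickness in A.
#'   Defaults: POPC 37, DMPC 35.
#' @param waters_per_lipid Hydration level in water molecules per lipid.
#'   Defaults: POPC 31, DMPC 26.6.
#' @param n_lipids Total lipid count across both leaflets (default 128,
#'   i.e. 64 per leaflet).
#' @param component_profiles Optional tibble with columns `component`,
#'   `mean_z`, `sd_z` describing upper-leaflet Gaussian z-profiles (in A,
#'   bilayer center at 0); the lower leaflet is mirrored. Required for lipids
#'   without a built-in map.
#' @param salt_molarity Salt concentration metadata in mol/L (default 0.1).
#' @param water_volume Per-water volume in A^3 used to convert hydration to
#'   slab thickness (default 30).
#'
#' @return An object of class `bilayer_model`: a list with fields `lipid_name`,
#'   `n_lipids`, `n_per_leaflet`, `area_per_lipid`, `box_x`, `box_y`, `box_z`,
#'   `phosphate_plane_upper`, `phosphate_plane_lower`, `component_profiles`,
#'   `waters_per_lipid`, `salt_molarity`, and `ions` (metadata counts).
#' @examples
#' popc <- build_bilayer_model("POPC")
#' popc$phosphate_plane_upper   # 18.5
#' popc$box_x * popc$box_y      # 64 * 65 = 4160 A^2
#' @export
build_bilayer_model <- function(lipid_name,
                                area_per_lipid = NULL,
                                thickness = NULL,
                                waters_per_lipid = NULL,
                                n_lipids = 128,
                                component_profiles = NULL,
                                salt_molarity = 0.1,
                                water_volume = 30) {
  defaults <- list(
    POPC = list(area = 65, thickness = 37, waters = 31, ions = c(cation = 9, anion = 9)),
    DMPC = list(area = 60, thickness = 35, waters = 26.6, ions = c(cation = 7, anion = 7))
  )
  known <- lipid_name %in% names(defaults)
  if (!known && is.null(component_profiles)) {
    abort(paste0(
      "No built-in component map for lipid '", lipid_name,
      "'; supply `component_profiles` (component, mean_z, sd_z) explicitly."
    ))
  }
  def <- if (known) defaults[[lipid_name]] else list(area = NULL, thickness = NULL, waters = NULL, ions = c(cation = NA_real_, anion = NA_real_))
  area_per_lipid <- area_per_lipid %||% def$area
  thickness <- thickness %||% def$thickness
  waters_per_lipid <- waters_per_lipid %||% def$waters
  stopifnot(
    "`area_per_lipid` must be a single positive number" =
      is.numeric(area_per_lipid) && length(area_per_lipid) == 1 && area_per_lipid > 0,
    "`thickness` must be a single positive number" =
      is.numeric(thickness) && length(thickness) == 1 && thickness > 0,
    "`waters_per_lipid` must be a single non-negative number" =
      is.numeric(waters_per_lipid) && length(waters_per_lipid) == 1 && waters_per_lipid >= 0,
    "`n_lipids` must be a positive even count" =
      is.numeric(n_lipids) && length(n_lipids) == 1 && n_lipids > 0 && n_lipids %% 2 == 0
  )

  n_per_leaflet <- n_lipids / 2
  lateral_area <- n_per_leaflet * area_per_lipid
  box_x <- box_y <- sqrt(lateral_area)
  half_thickness <- thickness / 2

  # total water volume spread over the two slabs flanking the bilayer
  slab_total <- n_lipids * waters_per_lipid * water_volume / lateral_area
  box_z <- thickness + slab_total

  if (is.null(component_profiles)) {
    component_profiles <- default_component_profiles(half_thickness)
    # degenerate hydration: keep default headgroup means inside the box
    component_profiles$mean_z <- pmin(component_profiles$mean_z,
                                      box_z / 2 - 1e-6)
  } else {
    component_profiles <- as_tibble(component_profiles)
    needed <- c("component", "mean_z", "sd_z")
    if (!all(needed %in% names(component_profiles))) {
      abort("`component_profiles` needs columns component, mean_z, sd_z")
    }
  }
  if (any(component_profiles$mean_z < 0 | component_profiles$mean_z >= box_z / 2)) {
    abort("component profile means must lie in [0, box_z/2) for the upper leaflet")
  }

  structure(
    list(
      lipid_name = lipid_name,
      n_lipids = n_lipids,
      n_per_leaflet = n_per_leaflet,
      area_per_lipid = area_per_lipid,
      box_x = box_x,
      box_y = box_y,
      box_z = box_z,
      thickness = thickness,
      phosphate_plane_upper = half_thickness,
      phosphate_plane_lower = -half_thickness,
      component_profiles = component_profiles,
      waters_per_lipid = waters_per_lipid,
      salt_molarity = salt_molarity,
      ions = def$ions
    ),
    class = "bilayer_model"
  )
}

# Upper-leaflet Gaussian z-profiles for the four lipid component bins.
# Means are tied to the phosphate plane; widths are coarse pseudo-atom
# spreads, not electron-density fits.
default_component_profiles <- function(half_thickness) {
  tibble(
    component = c("choline", "phosphate", "glycerol", "tail"),
    mean_z = c(half_thickness + 2, half_thickness, half_thickness - 4, half_thickness / 2),
    sd_z = c(2.5, 1.5, 2, half_thickness / 4)
  )
}

#' Lateral membrane area of a bilayer model
#'
#' @param bilayer A `bilayer_model`.
#' @return Lateral area A = box_x * box_y in A^2.
#' @export
lateral_area <- function(bilayer) {
  stopifnot(inherits(bilayer, "bilayer_model"))
  bilayer$box_x * bilayer$box_y
}

#' Water-layer thickness of a bilayer model
#'
#' The thickness L_z of the water slab through which a solute diffuses before
#' reaching the membrane surface. `"one"` (default) returns the slab on one
#' side of the bilayer, `"both"` the total water thickness in the box.
#'
#' @param bilayer A `bilayer_model`.
#' @param sides `"one"` or `"both"`.
#' @return L_z in A.
#' @export
water_layer_thickness <- function(bilayer, sides = c("one", "both")) {
  stopifnot(inherits(bilayer, "bilayer_model"))
  sides <- match.arg(sides)
  total <- bilayer$box_z - bilayer$thickness
  if (sides == "one") total / 2 else total
}

#' @export
print.bilayer_model <- function(x, ...) {
  cat("<bilayer_model> ", x$lipid_name, "\n", sep = "")
  cat("  lipids:      ", x$n_lipids, " (", x$n_per_leaflet, " per leaflet)\n", sep = "")
  cat(sprintf("  box:          %.2f x %.2f x %.2f A\n", x$box_x, x$box_y, x$box_z))
  cat(sprintf("  phosphate planes: +/- %.2f A\n", x$phosphate_plane_upper))
  cat(sprintf("  hydration:    %.1f waters/lipid, %.2f M salt\n",
              x$waters_per_lipid, x$salt_molarity))
  invisible(x)
}

#' @describeIn build_bilayer_model Tidy the component z-profiles (both
#'   leaflets) into a tibble with columns component, leaflet, mean_z, sd_z.
#' @param x A `bilayer_model`.
#' @param ... Unused.
#' @export
tidy.bilayer_model <- function(x, ...) {
  up <- dplyr::mutate(x$component_profiles, leaflet = "upper")
  lo <- dplyr::mutate(x$component_profiles, leaflet = "lower", mean_z = -.data$mean_z)
  dplyr::select(
    dplyr::bind_rows(up, lo),
    "component", "leaflet", "mean_z", "sd_z"
  )
}
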