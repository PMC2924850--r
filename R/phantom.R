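#' Short-axis cine phantom geometry
#'
#' Raster and slice settings for the synthetic cine stack: square pixels,
#' parallel short-axis slices of fixed thickness separated by an
#' inter-slice gap (defaults 6 mm / 4 mm, a standard SSFP cine
#' prescription). The cavity is modeled as a truncated prolate ellipsoid:
#' per-slice radii taper from near-annulus at the base to near-zero at the
#' apex, and the basal truncation (`annulus_cut`) excludes the portion
#' above the mitral annulus plane.
#'
#' @param pixel_spacing_mm In-plane pixel size, mm. The default 1 mm is a
#'   typical reconstructed (interpolated) cine pixel; acquisition-grid
#'   resolution (e.g. 1.9 x 1.4 mm) can be set explicitly.
#' @param img_size Image width/height in pixels.
#' @param slice_thickness_mm,slice_gap_mm Slice thickness and inter-slice
#'   gap, mm.
#' @param n_slices Number of short-axis slices (>= 3).
#' @param include_gap Whether the effective spacing used in volume
#'   summation is thickness + gap (contiguous-coverage assumption) or
#'   thickness alone.
#' @param annulus_cut,apex_cut Long-axis truncation fractions in `[0, 1)`:
#'   the slice stack samples the ellipsoid between `annulus_cut` (base)
#'   and `apex_cut` (apex) of the normalized long axis.
#' @return A `cine_geometry` list.
#' @export
cine_geometry <- function(pixel_spacing_mm = 1, img_size = 160,
                          slice_thickness_mm = 6, slice_gap_mm = 4,
                          n_slices = 10, include_gap = TRUE,
                          annulus_cut = 0.08, apex_cut = 0.95) {
  if (pixel_spacing_mm <= 0 || img_size < 16 || slice_thickness_mm <= 0 ||
    slice_gap_mm < 0 || n_slices < 3) {
    abort("invalid phantom geometry", class = "lvfill_bad_geometry")
  }
  structure(
    list(
      pixel_spacing_mm = pixel_spacing_mm, img_size = as.integer(img_size),
      slice_thickness_mm = slice_thickness_mm, slice_gap_mm = slice_gap_mm,
      n_slices = as.integer(n_slices), include_gap = include_gap,
      annulus_cut = annulus_cut, apex_cut = apex_cut
    ),
    class = "cine_geometry"
  )
}

effective_spacing <- function(geometry) {
  geometry$slice_thickness_mm +
    if (geometry$include_gap) geometry$slice_gap_mm else 0
}

# Relative radius profile of the truncated ellipsoid at each slice center.
slice_profile <- function(geometry) {
  x <- seq(geometry$annulus_cut, geometry$apex_cut,
    length.out = geometry$n_slices
  )
  sqrt(1 - x^2)
}

#' Rasterize a synthetic patient into a multi-slice cine stack
#'
#' Evaluates [volume_function()] at each cardiac phase and draws, per
#' slice, a bright blood-pool disk whose radius follows the
#' truncated-ellipsoid taper, scaled so the analytic stack volume
#' (sum of disk areas times effective slice spacing) equals the model
#' volume at that phase exactly. A dimmer myocardial ring (intensity 0.35
#' vs blood 1.0, background 0.05) surrounds each disk so thresholding is
#' non-trivial.
#'
#' @inheritParams volume_function
#' @param geometry A [cine_geometry()].
#' @param n_phases Number of cine phases.
#' @return A `cine_stack`: list with `frames` (per-phase 3-D arrays
#'   `[x, y, slice]`), `phase_times`, `radii_mm` (phase x slice analytic
#'   radii), `analytic_areas_mm2`, `analytic_volumes_ml`, the geometry,
#'   and `rr_ms`.
#' @export
rasterize_stack <- function(truth, geometry = cine_geometry(), n_phases = 20) {
  stopifnot(inherits(truth, "patient_truth"), inherits(geometry, "cine_geometry"))
  prof <- slice_profile(geometry)
  spacing <- effective_spacing(geometry)
  times <- (seq_len(n_phases) - 1) * truth$rr_ms / n_phases
  vols <- volume_function(truth)(times)
  # R such that sum(pi * (R * prof)^2) * spacing == V (in mm^3)
  R <- sqrt(vols * 1000 / (pi * spacing * sum(prof^2)))
  r_max_allowed <- (geometry$img_size / 2 - 2) * geometry$pixel_spacing_mm
  if (max(R) * max(prof) + 8 > r_max_allowed) {
    abort("requested volume not representable within the raster bounds",
      class = "lvfill_raster_overflow"
    )
  }
  px <- geometry$pixel_spacing_mm
  coord <- (seq_len(geometry$img_size) - (geometry$img_size + 1) / 2) * px
  d2 <- outer(coord^2, coord^2, `+`) # squared distance from center, mm^2
  radii <- outer(R, prof) # phase x slice
  frames <- lapply(seq_len(n_phases), function(p) {
    arr <- array(0.05, dim = c(geometry$img_size, geometry$img_size, geometry$n_slices))
    for (s in seq_len(geometry$n_slices)) {
      r <- radii[p, s]
      ring <- d2 <= (r + 8)^2
      blood <- d2 <= r^2
      sl <- arr[, , s]
      sl[ring] <- 0.35
      sl[blood] <- 1
      arr[, , s] <- sl
    }
    arr
  })
  structure(
    list(
      frames = frames, phase_times = times, rr_ms = truth$rr_ms,
      radii_mm = radii,
      analytic_areas_mm2 = pi * radii^2,
      analytic_volumes_ml = vols,
      geometry = geometry
    ),
    class = "cine_stack"
  )
}

# 4-connected region growth from a seed on a logical mask, by iterative
# frontier propagation (vectorized shifts; O(diameter) passes).
region_grow <- function(mask, seed) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  reg <- matrix(FALSE, nr, nc)
  if (!mask[seed[1], seed[2]]) {
    return(reg)
  }
  reg[seed[1], seed[2]] <- TRUE
  repeat {
    grown <- reg
    grown[-1, ] <- grown[-1, ] | reg[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | reg[-1, ]
    grown[, -1] <- grown[, -1] | reg[, -nc]
    grown[, -nc] <- grown[, -nc] | reg[, -1]
    grown <- grown & mask
    if (!any(grown & !reg)) {
      return(grown)
    }
    reg <- grown
  }
}

#' Stand-in blood-pool segmentation of a cine phantom stack
#'
#' A deliberately simple segmentation: per slice and phase, the image is
#' thresholded at a fraction of the stack's maximum intensity (strictly
#' greater-than, so a threshold of 1 selects nothing) and a 4-connected
#' region is grown from the seed point. Cavity area is the grown pixel
#' count times pixel area; per-phase volume is the slice-area summation of
#' [stack_volume()].
#'
#' @param stack A [rasterize_stack()] output.
#' @param seed_point Pixel coordinate `c(row, col)` inside the blood pool;
#'   defaults to the image center.
#' @param intensity_threshold Threshold as a fraction of the stack maximum.
#' @return A `segmentation_result`: list with `areas_mm2` (phase x slice),
#'   `volumes_ml` (per phase), `curve` (a segmented `volume_curve`).
#' @export
segment_stack <- function(stack, seed_point = NULL, intensity_threshold = 0.5) {
  stopifnot(inherits(stack, "cine_stack"))
  g <- stack$geometry
  seed_point <- seed_point %||% rep((g$img_size + 1) %/% 2, 2)
  if (any(seed_point < 1) || any(seed_point > g$img_size)) {
    abort("seed point lies outside the image", class = "lvfill_bad_seed")
  }
  top <- max(vapply(stack$frames, max, numeric(1)))
  ref_slice <- which.max(stack$radii_mm[1, ])
  if (stack$frames[[1]][seed_point[1], seed_point[2], ref_slice] < 0.5 * top) {
    abort("seed point does not lie in the blood pool at the reference phase",
      class = "lvfill_bad_seed"
    )
  }
  cut <- intensity_threshold * top
  px_area <- g$pixel_spacing_mm^2
  areas <- matrix(0, length(stack$frames), g$n_slices)
  for (p in seq_along(stack$frames)) {
    for (s in seq_len(g$n_slices)) {
      mask <- stack$frames[[p]][, , s] > cut
      areas[p, s] <- sum(region_grow(mask, seed_point)) * px_area
    }
  }
  vols <- apply(areas, 1, stack_volume,
    thickness_mm = g$slice_thickness_mm,
    gap_mm = g$slice_gap_mm, include_gap = g$include_gap
  )
  structure(
    list(
      areas_mm2 = areas, volumes_ml = vols,
      curve = new_volume_curve(stack$phase_times, vols, stack$rr_ms,
        provenance = "segmented"
      )
    ),
    class = "segmentation_result"
  )
}

#' Slice-summation ventricular volume
#'
#' Simpson-style summation of short-axis cavity areas: volume is the sum
#' of per-slice areas times the effective slice spacing. With
#' `include_gap = TRUE` (default) the spacing is thickness + gap, treating
#' each slice's area as representative of its full coverage interval;
#' with `FALSE` only the imaged thickness contributes.
#'
#' @param areas_mm2 Per-slice cavity areas, mm^2 (non-negative).
#' @param thickness_mm,gap_mm Slice thickness and inter-slice gap, mm.
#' @param include_gap Include the gap in the effective spacing?
#' @return Volume in ml.
#' @export
#' @examples
#' stack_volume(c(1000, 1000), 6, 4) # 20 ml
stack_volume <- function(areas_mm2, thickness_mm = 6, gap_mm = 4,
                         include_gap = TRUE) {
  if (any(areas_mm2 < 0) || thickness_mm <= 0 || gap_mm < 0) {
    abort("areas must be >= 0 and slice dimensions positive",
      class = "lvfill_bad_areas"
    )
  }
  spacing <- thickness_mm + if (include_gap) gap_mm else 0
  sum(areas_mm2) * spacing / 1000
}

#' Write a cine stack to disk
#'
#' One multi-slice TIFF per phase plus a JSON geometry manifest. Requires
#' the `tiff` package.
#'
#' @param stack A `cine_stack`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cine_stack <- function(stack, dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to write cine stacks",
      class = "lvfill_missing_tiff"
    )
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in seq_along(stack$frames)) {
    slices <- lapply(
      seq_len(dim(stack$frames[[p]])[3]),
      function(s) stack$frames[[p]][, , s]
    )
    tiff::writeTIFF(slices, file.path(dir, sprintf("phase%03d.tiff", p)))
  }
  g <- stack$geometry
  jsonlite::write_json(
    list(
      pixel_spacing_mm = g$pixel_spacing_mm,
      slice_thickness_mm = g$slice_thickness_mm,
      slice_gap_mm = g$slice_gap_mm, n_slices = g$n_slices,
      include_gap = g$include_gap,
      phase_times_ms = stack$phase_times, rr_ms = stack$rr_ms
    ),
    file.path(dir, "geometry.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}
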