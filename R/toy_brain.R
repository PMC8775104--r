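# Toy brain geometry: concentric perturbed-ellipsoid gray/white and pial
# surfaces with a solid-angle-sector parcellation. Non-spherical on purpose:
# on a sphere the interface normal is everywhere radial and feature
# f2 = cos(r, n) degenerates to 1.

#' Build a toy brain model
#'
#' Constructs concentric perturbed-ellipsoid surfaces (pial strictly outside
#' the gray/white interface) and a sector parcellation: `n_pairs` cortical
#' azimuth sectors, each paired with an adjacent white-matter rim of
#' thickness `rim_mm` directly beneath it, plus `n_subcortical` deep sectors
#' in a central band outside the exclusion sphere. Region volumes are
#' computed by deterministic solid-angle quadrature of the bounding radii,
#' so they are consistent with the sampling geometry used by
#' [simulate_cohort()].
#'
#' @param n_pairs number of cortex/white-rim sector pairs (even, >= 2).
#' @param n_subcortical number of subcortical sectors (>= 0).
#' @param subdivisions icosphere subdivision level for both meshes
#'   (3 gives 642 vertices per surface).
#' @param semi_axes ellipsoid semi-axes of the gray/white interface, mm.
#' @param perturb_amp relative amplitude of the smooth radial perturbation.
#' @param rim_mm white-matter rim thickness beneath the interface, mm.
#' @param subcort_band radial band `[lo, hi]` of the subcortical sectors, mm;
#'   `lo` must be at or above `exclusion_radius`.
#' @param exclusion_radius central exclusion sphere radius, mm.
#' @return A [brain_model()] whose `"toy_geometry"` attribute carries the
#'   analytic radius functions and sector boundaries used for sampling.
#' @export
build_toy_brain <- function(n_pairs = 8, n_subcortical = 3, subdivisions = 3,
                            semi_axes = c(70, 60, 55), perturb_amp = 0.04,
                            rim_mm = 5, subcort_band = c(33, 45),
                            exclusion_radius = 30) {
  stopifnot(n_pairs >= 2, n_pairs %% 2 == 0, n_subcortical >= 0,
            subcort_band[1] >= exclusion_radius,
            subcort_band[2] < min(semi_axes) * (1 - perturb_amp) - rim_mm)

  r_gw <- function(u) {
    u <- matrix(u, ncol = 3)
    re <- 1 / sqrt((u[, 1] / semi_axes[1])^2 + (u[, 2] / semi_axes[2])^2 +
                     (u[, 3] / semi_axes[3])^2)
    theta <- acos(pmin(1, pmax(-1, u[, 3])))
    phi <- atan2(u[, 2], u[, 1])
    re * (1 + perturb_amp * sin(2 * theta) * cos(3 * phi))
  }
  thickness <- function(u) {
    u <- matrix(u, ncol = 3)
    theta <- acos(pmin(1, pmax(-1, u[, 3])))
    phi <- atan2(u[, 2], u[, 1])
    2.5 + 0.5 * (1 + sin(theta) * cos(2 * phi))
  }
  r_pial <- function(u) r_gw(u) + thickness(u)

  base <- icosphere(subdivisions)
  u <- base$vertices
  gw_mesh <- trimesh(u * r_gw(u), base$faces)
  pial_mesh <- trimesh(u * r_pial(u), base$faces)

  az_breaks <- seq(-pi, pi, length.out = n_pairs + 1)
  az_centers <- (az_breaks[-1] + az_breaks[-(n_pairs + 1)]) / 2
  hemi <- ifelse(abs(cos(az_centers)) < 1e-12, "midline",
                 ifelse(cos(az_centers) > 0, "right", "left"))

  # solid-angle quadrature of sector volumes: dV = (r_out^3 - r_in^3)/3 dOmega
  nphi <- 36 * n_pairs
  nct <- 64
  phi_g <- -pi + (seq_len(nphi) - 0.5) * (2 * pi / nphi)
  ct_g <- -1 + (seq_len(nct) - 0.5) * (2 / nct)
  grid <- expand.grid(phi = phi_g, ct = ct_g)
  st <- sqrt(1 - grid$ct^2)
  ug <- cbind(st * cos(grid$phi), st * sin(grid$phi), grid$ct)
  dOmega <- (2 * pi / nphi) * (2 / nct)
  rg <- r_gw(ug)
  rp <- r_pial(ug)
  bin <- findInterval(grid$phi, az_breaks, rightmost.closed = TRUE)
  vol_ctx <- tapply((rp^3 - rg^3) / 3 * dOmega, bin, sum)
  vol_wm <- tapply((rg^3 - (rg - rim_mm)^3) / 3 * dOmega, bin, sum)

  regions <- data.frame(
    region_id = seq_len(2 * n_pairs + n_subcortical),
    name = c(sprintf("ctx_%02d", seq_len(n_pairs)),
             sprintf("wm_%02d", seq_len(n_pairs)),
             if (n_subcortical > 0) sprintf("subcort_%02d", seq_len(n_subcortical))),
    hemisphere = c(hemi, hemi, rep("midline", n_subcortical)),
    tissue = c(rep("cortex", n_pairs), rep("white_rim", n_pairs),
               rep("subcortical", n_subcortical)),
    volume_mm3 = c(as.numeric(vol_ctx), as.numeric(vol_wm),
                   rep((2 / n_subcortical) * pi *  # full cos-theta band
                         (subcort_band[2]^3 - subcort_band[1]^3) * 2 / 3,
                       n_subcortical))[seq_len(2 * n_pairs + n_subcortical)],
    paired_region_id = c(n_pairs + seq_len(n_pairs), seq_len(n_pairs),
                         rep(NA_integer_, n_subcortical)),
    stringsAsFactors = FALSE)

  model <- brain_model(regions, gw_mesh, pial_mesh,
                       sphere_center = c(0, 0, 0),
                       exclusion_radius = exclusion_radius)
  attr(model, "toy_geometry") <- list(
    n_pairs = n_pairs, n_subcortical = n_subcortical,
    az_breaks = az_breaks, r_gw = r_gw, r_pial = r_pial,
    thickness = thickness, rim_mm = rim_mm, subcort_band = subcort_band)
  model
}

# subcortical sector azimuth breaks (reuses the full circle split S ways)
subcort_breaks <- function(geom) {
  seq(-pi, pi, length.out = geom$n_subcortical + 1)
}

# radial band [lo, hi] of a region along direction u, from the toy geometry
region_radial_band <- function(region_row, geom, u) {
  rg <- geom$r_gw(u)
  switch(region_row$tissue,
         cortex = cbind(rg, geom$r_pial(u)),
         white_rim = cbind(rg - geom$rim_mm, rg),
         subcortical = cbind(rep(geom$subcort_band[1], nrow(matrix(u, ncol = 3))),
                             rep(geom$subcort_band[2], nrow(matrix(u, ncol = 3)))))
}
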