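# Closed-form sizing arithmetic for the term gravid uterus: a 4.5 kg
# conceptus (fetus + placenta + amniotic fluid) at unit density fills 4.5 L;
# a sphere of that volume has radius ~10.2 cm and area ~1300 cm^2, while the
# real organ is an oblate spheroid with area ~1900 cm^2. A "region" is the
# ~8 cm x 8 cm patch one action-potential burst can recruit, so the sphere
# carries 20-21 regions and the spheroid roughly 25-30.

#' Radius of a sphere of given volume
#'
#' @param volume sphere volume in cm^3 (> 0).
#' @return Radius in cm: `(3 V / (4 pi))^(1/3)`.
#' @examples
#' sphere_radius_from_volume(4500)   # ~10.2 cm for the term gravid uterus
#' @export
sphere_radius_from_volume <- function(volume) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("sphere_radius_from_volume: 'volume' must be positive", call. = FALSE)
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Surface area of a sphere
#'
#' @param radius sphere radius in cm (> 0).
#' @return Area in cm^2: `4 pi r^2`.
#' @examples
#' sphere_surface_area(sphere_radius_from_volume(4500))  # ~1300 cm^2
#' @export
sphere_surface_area <- function(radius) {
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("sphere_surface_area: 'radius' must be positive", call. = FALSE)
  4 * pi * radius^2
}

#' Edge length of a square region tiling a given area
#'
#' @param total_area wall surface area in cm^2.
#' @param n_regions number of regions tiling it.
#' @return Edge length in cm: `sqrt(total_area / n_regions)`.
#' @examples
#' region_edge_length(1900, 64)  # ~5.5 cm
#' region_edge_length(1900, 9)   # ~14.5 cm
#' @export
region_edge_length <- function(total_area, n_regions) {
  stopifnot(all(total_area > 0), all(n_regions > 0))
  sqrt(total_area / n_regions)
}

#' Time to recruit all tissue within a region
#'
#' Intra-regional recruitment is by action-potential propagation at about
#' 3 cm/s, so a region is fully recruited in `edge_length / speed` seconds —
#' under 5 s even for the 9-region tiling, which justifies treating each
#' region as uniformly active at the ~5 s step of the automaton.
#'
#' @param edge_length region edge in cm.
#' @param speed propagation speed in cm/s.
#' @return Recruitment time in seconds.
#' @examples
#' recruitment_time(region_edge_length(1900, 9))  # < 5 s
#' @export
recruitment_time <- function(edge_length, speed = 3) {
  stopifnot(all(edge_length > 0), all(speed > 0))
  edge_length / speed
}

#' Number of regions covering a surface
#'
#' @param total_area wall surface area in cm^2.
#' @param region_area area of one region in cm^2 (e.g. 64 for 8 cm x 8 cm).
#' @return Unrounded region count `total_area / region_area`; callers floor
#'   or ceiling as needed.
#' @examples
#' regions_on_surface(1300, 64)  # ~20.3: a spherical uterus holds 20-21
#' @export
regions_on_surface <- function(total_area, region_area) {
  stopifnot(all(total_area > 0), all(region_area > 0))
  total_area / region_area
}

#' Baseline-to-maximal pressure ratio
#'
#' Intrauterine pressure catheters show about 15 torr between contractions
#' and about 300 torr at the strongest achievable contraction, a 1/20 ratio;
#' on the simulation's 0..10 activity scale this is what puts the reasonable
#' minimum pressure near 0.5.
#'
#' @param baseline resting pressure, torr.
#' @param maximum maximal pressure, torr.
#' @return The ratio `baseline / maximum`.
#' @examples
#' baseline_pressure_fraction()  # 0.05 = 1/20
#' @export
baseline_pressure_fraction <- function(baseline = 15, maximum = 300) {
  stopifnot(baseline > 0, maximum > 0)
  baseline / maximum
}

#' Full uterine-geometry summary table
#'
#' Convenience table combining the sizing arithmetic for a given uterine
#' volume, spheroid area, and region count: sphere radius and area, implied
#' region counts for both shapes, region edge length and intra-regional
#' recruitment time.
#'
#' @param volume uterine content volume in cm^3.
#' @param spheroid_area oblate-spheroid wall area in cm^2.
#' @param region_area area of one action-potential region in cm^2.
#' @param n_regions region count used for the edge/recruitment lines.
#' @param speed action-potential propagation speed in cm/s.
#' @return A data.frame of named quantities with units.
#' @export
uterine_geometry <- function(volume = 4500, spheroid_area = 1900,
                             region_area = 64, n_regions = 64, speed = 3) {
  r <- sphere_radius_from_volume(volume)
  sa <- sphere_surface_area(r)
  edge <- region_edge_length(spheroid_area, n_regions)
  data.frame(
    quantity = c("sphere_radius", "sphere_area", "regions_on_sphere",
                 "regions_on_spheroid", "region_edge", "recruitment_time"),
    value = c(r, sa, regions_on_surface(sa, region_area),
              regions_on_surface(spheroid_area, region_area), edge,
              recruitment_time(edge, speed)),
    unit = c("cm", "cm^2", "regions", "regions", "cm", "s"))
}
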