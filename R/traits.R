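#' Volume of a cylindrical increment core
#'
#' Wood cores extracted with an increment borer are cylinders; volume is
#' pi * (diameter/2)^2 * length.
#'
#' @param length Core length, cm; must be > 0.
#' @param diameter Core cross-section diameter, cm; must be > 0.
#' @return Volume in cm^3. Vectorized.
#' @examples
#' core_volume(10, 1)  # 7.853982
#' @export
core_volume <- function(length, diameter) {
  stopifnot(is.numeric(length), is.numeric(diameter))
  if (any(!is.finite(length)) || any(length <= 0))
    stop("core 'length' must be > 0", call. = FALSE)
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("core 'diameter' must be > 0", call. = FALSE)
  pi * (diameter / 2)^2 * length
}

#' Wood density from dry mass and fresh volume
#'
#' Oven-dry mass divided by fresh core volume, g cm^-3 (the wood-economics
#' convention; a density near 0.56 g cm^-3 is typical for the study species).
#'
#' @param dry_mass Oven-dry mass, g; must be >= 0.
#' @param volume Fresh volume, cm^3; must be > 0.
#' @return Density in g cm^-3. Vectorized.
#' @export
wood_density <- function(dry_mass, volume) {
  stopifnot(is.numeric(dry_mass), is.numeric(volume))
  if (any(!is.finite(dry_mass)) || any(dry_mass < 0))
    stop("'dry_mass' must be >= 0", call. = FALSE)
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("'volume' must be > 0", call. = FALSE)
  dry_mass / volume
}

#' Leaf mass per area
#'
#' Leaf dry mass divided by one-sided leaf area, g m^-2. A tree-level LMA is
#' the unweighted mean over that tree's sampled leaves (conventionally three
#' intact, sun-exposed leaves); see [tree_lma()].
#'
#' @param dry_mass Leaf dry mass, g; must be >= 0.
#' @param area Leaf area, m^2; must be > 0.
#' @return LMA in g m^-2. Vectorized.
#' @export
leaf_mass_per_area <- function(dry_mass, area) {
  stopifnot(is.numeric(dry_mass), is.numeric(area))
  if (any(!is.finite(dry_mass)) || any(dry_mass < 0))
    stop("leaf 'dry_mass' must be >= 0", call. = FALSE)
  if (any(!is.finite(area)) || any(area <= 0))
    stop("leaf 'area' must be > 0", call. = FALSE)
  dry_mass / area
}

#' @rdname leaf_mass_per_area
#' @param lma_values Per-leaf LMA values for one tree.
#' @export
tree_lma <- function(lma_values) {
  stopifnot(is.numeric(lma_values), length(lma_values) >= 1L)
  mean(lma_values)
}

#' Standardize a trait series
#'
#' Z-scores a series of trait values, either against a supplied
#' [trait_standardization()] or against the series' own mean and SD. The
#' standardization actually used is returned so raw-scale back-transforms are
#' exact.
#'
#' @param values Numeric trait series.
#' @param std A [trait_standardization()], or `NULL` to estimate from
#'   `values` (requires length >= 2 and nonzero variance).
#' @return A list with `z` (the z-scored series) and `std` (the
#'   `trait_standardization` used).
#' @examples
#' standardize_trait(0.728, default_wd_standardization())$z  # ~1.5
#' @export
standardize_trait <- function(values, std = NULL) {
  stopifnot(is.numeric(values))
  if (is.null(std)) {
    if (length(values) < 2L)
      stop("need >= 2 values to estimate a standardization", call. = FALSE)
    s <- stats::sd(values)
    if (!is.finite(s) || s == 0)
      stop("trait series has zero variance; supply 'std' explicitly",
           call. = FALSE)
    std <- trait_standardization(mean(values), s)
  }
  if (!inherits(std, "trait_standardization"))
    stop("'std' must be a trait_standardization", call. = FALSE)
  list(z = (values - std$mean) / std$sd, std = std)
}

#' @rdname standardize_trait
#' @param z Z-scored values to map back to the raw scale.
#' @export
unstandardize_trait <- function(z, std) {
  stopifnot(inherits(std, "trait_standardization"), is.numeric(z))
  z * std$sd + std$mean
}

#' Compute per-tree traits from raw measurement tables
#'
#' Takes raw increment-core and leaf measurements and returns one wood
#' density and one LMA per tree. Expected columns:
#' `cores`: `tree_id`, `core_length_cm`, `core_diameter_cm`,
#' `core_dry_mass_g`; `leaves`: `tree_id`, `leaf_area_m2`, `leaf_dry_mass_g`
#' (one row per leaf).
#'
#' @param cores Data frame of core measurements (one row per tree).
#' @param leaves Data frame of leaf measurements (several rows per tree).
#' @return Data frame with `tree_id`, `wd` (g cm^-3), `lma` (g m^-2).
#' @export
compute_traits <- function(cores, leaves) {
  need <- c("tree_id", "core_length_cm", "core_diameter_cm", "core_dry_mass_g")
  miss <- setdiff(need, names(cores))
  if (length(miss))
    stop("cores table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  need <- c("tree_id", "leaf_area_m2", "leaf_dry_mass_g")
  miss <- setdiff(need, names(leaves))
  if (length(miss))
    stop("leaves table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  vol <- core_volume(cores$core_length_cm, cores$core_diameter_cm)
  wd <- data.frame(tree_id = cores$tree_id,
                   wd = wood_density(cores$core_dry_mass_g, vol))
  per_leaf <- leaf_mass_per_area(leaves$leaf_dry_mass_g, leaves$leaf_area_m2)
  lma <- stats::aggregate(list(lma = per_leaf),
                          by = list(tree_id = leaves$tree_id), FUN = mean)
  merge(wd, lma, by = "tree_id", all = TRUE)
}
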