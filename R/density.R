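#' Gel recipe and geometry constructors
#'
#' Light-weight validated lists describing a streptavidin-functionalized
#' polyacrylamide gel: its chemistry (`gel_recipe`) and its cast geometry
#' (`gel_geometry`). Defaults are the 6.4 kPa formulation (5% acrylamide,
#' streptavidin-acrylamide at 1/100000 molar ratio to acrylamide) cast as a
#' 15 mm disc that swells ~40% on hydration, with biotinylated ligands able
#' to reach streptavidin only in the outermost 10 nm of the gel (about one
#' streptavidin diameter, and below the reported pore size).
#'
#' @param acrylamide_pct Acrylamide concentration, % w/v (> 0).
#' @param bis_pct Bis-acrylamide concentration, % w/v (metadata only;
#'   crosslinker is excluded from the monomer molarity).
#' @param strept_molar_ratio Streptavidin-acrylamide conjugate per
#'   acrylamide monomer, molar (in (0, 1)).
#' @param acrylamide_molar_mass Acrylamide monomer molar mass, g/mol
#'   (71.08).
#' @return A named list of class `gel_recipe` / `gel_geometry`.
#' @export
gel_recipe <- function(acrylamide_pct, bis_pct = NA_real_,
                       strept_molar_ratio = 1e-5,
                       acrylamide_molar_mass = .ACRYLAMIDE_MOLAR_MASS) {
  check_number(acrylamide_pct, "acrylamide_pct", min = 0, strict_min = TRUE)
  check_number(strept_molar_ratio, "strept_molar_ratio", min = 0, max = 1,
               strict_min = TRUE)
  check_number(acrylamide_molar_mass, "acrylamide_molar_mass", min = 0,
               strict_min = TRUE)
  structure(list(acrylamide_pct = acrylamide_pct, bis_pct = bis_pct,
                 strept_molar_ratio = strept_molar_ratio,
                 acrylamide_molar_mass = acrylamide_molar_mass),
            class = "gel_recipe")
}

#' @rdname gel_recipe
#' @param disc_diameter_mm Diameter of the gel disc, mm.
#' @param hydrated_thickness_um Hydrated gel thickness, um.
#' @param swelling_factor Hydrated/mix volume ratio (>= 1; 1.4 for ~40%
#'   swelling).
#' @param accessible_depth_nm Depth of the surface layer whose streptavidin
#'   is reachable by biotinylated ligands, nm.
#' @export
gel_geometry <- function(disc_diameter_mm = 15, hydrated_thickness_um = 50,
                         swelling_factor = 1.4, accessible_depth_nm = 10) {
  check_number(disc_diameter_mm, "disc_diameter_mm", min = 0, strict_min = TRUE)
  check_number(hydrated_thickness_um, "hydrated_thickness_um", min = 0,
               strict_min = TRUE)
  check_number(swelling_factor, "swelling_factor", min = 1)
  check_number(accessible_depth_nm, "accessible_depth_nm", min = 0,
               strict_min = TRUE)
  structure(list(disc_diameter_mm = disc_diameter_mm,
                 hydrated_thickness_um = hydrated_thickness_um,
                 swelling_factor = swelling_factor,
                 accessible_depth_nm = accessible_depth_nm),
            class = "gel_geometry")
}

#' Hydrated gel volume
#'
#' Volume of the hydrated gel disc: pi (diameter/2)^2 x thickness.
#'
#' @param geometry A [gel_geometry()].
#' @return Volume in uL (a 15 mm disc of 50 um gives 8.84 uL; 25 um gives
#'   4.42 uL).
#' @export
hydrated_volume <- function(geometry) {
  r_mm <- geometry$disc_diameter_mm / 2
  # mm^2 x um = nL; /1000 -> uL
  pi * r_mm^2 * geometry$hydrated_thickness_um / 1000
}

#' Polymerization-mix volume from hydrated volume
#'
#' The hydrated gel is `swelling_factor` times the initial polymerization
#' mix, so the cast mix volume is the hydrated volume divided by it.
#'
#' @param hydrated_ul Hydrated volume, uL.
#' @param swelling_factor Hydrated/mix volume ratio (>= 1).
#' @return Mix volume, uL.
#' @export
mix_volume <- function(hydrated_ul, swelling_factor = 1.4) {
  if (any(hydrated_ul <= 0)) abort("hydrated volume must be positive")
  check_number(swelling_factor, "swelling_factor", min = 1)
  hydrated_ul / swelling_factor
}

#' Accessible streptavidin surface density
#'
#' Theoretical surface density of streptavidin-acrylamide reachable by
#' biotinylated ligands, assuming (1) all conjugate in the mix polymerizes
#' into the gel, (2) hydration dilutes it by the swelling factor, and
#' (3) only the outermost `accessible_depth_nm` of gel is reachable.
#' The chain is: acrylamide molarity = 10 x %w/v / molar mass (mol/L);
#' times the conjugate molar ratio; divided by the swelling factor; times
#' Avogadro's number (molecules/L -> molecules/um^3); times the accessible
#' depth. Disc diameter and thickness cancel, so the density is independent
#' of them.
#'
#' @param recipe A [gel_recipe()].
#' @param geometry A [gel_geometry()].
#' @return Density in molecules/um^2 (about 30 for the 5% acrylamide,
#'   1/100000 ratio formulation).
#' @export
site_density <- function(recipe, geometry) {
  # % w/v = g/100 mL -> g/L needs x10
  acrylamide_molar <- 10 * recipe$acrylamide_pct / recipe$acrylamide_molar_mass
  strept_molar_mix <- acrylamide_molar * recipe$strept_molar_ratio
  strept_molar_gel <- strept_molar_mix / geometry$swelling_factor
  per_um3 <- strept_molar_gel * .N_AVOGADRO * 1e-15   # 1 L = 1e15 um^3
  per_um3 * geometry$accessible_depth_nm * 1e-3       # nm -> um
}

#' Surface density of a minority coated species
#'
#' When the gel is coated with a molar mixture of biotinylated species --
#' e.g. 10 parts anti-CD28 + ICAM-1 per 1 part anti-CD3 -- the minority
#' species density is derived from the total accessible site density by
#' dividing by the majority fold (the `"fold"` convention: 30/um^2 at 1:10
#' gives 3/um^2). The alternative `"partition"` convention splits total
#' sites 1:(fold), giving site_density/(1 + fold); both are available, the
#' fold convention is the default.
#'
#' @param site_density_um2 Total accessible site density, molecules/um^2.
#' @param majority_fold Molar fold of the majority species per minority
#'   molecule (> 0; 10 for a 1:10 ratio).
#' @param convention `"fold"` (default) or `"partition"`.
#' @return Minority species density, molecules/um^2.
#' @export
species_density <- function(site_density_um2, majority_fold,
                            convention = c("fold", "partition")) {
  convention <- match.arg(convention)
  if (any(site_density_um2 < 0)) abort("site density must be non-negative")
  check_number(majority_fold, "majority_fold", min = 0, strict_min = TRUE)
  switch(convention,
         fold = site_density_um2 / majority_fold,
         partition = site_density_um2 / (1 + majority_fold))
}

#' Full ligand surface-density report for a gel formulation
#'
#' Runs the whole density chain -- hydrated and mix volumes, accessible
#' streptavidin site density, and minority-species density at the given
#' coating ratio -- and also reports the densities obtained when the
#' intermediate volumes are rounded the way they appear in lab notebooks
#' (volumes to one decimal, mix volumes to integers), which is how printed
#' ranges typically arise.
#'
#' @inheritParams site_density
#' @param coating_fold Majority:minority molar fold of the coating mix
#'   (default 10, i.e. 10 anti-CD28 + ICAM-1 : 1 anti-CD3).
#' @return A one-row tibble with `hydrated_volume_ul`, `mix_volume_ul`,
#'   `site_density_um2`, `minority_density_um2` (fold convention),
#'   `minority_density_partition_um2`, and rounded-volume variants
#'   `site_density_rounded_um2`.
#' @export
density_report <- function(recipe, geometry, coating_fold = 10) {
  v_hyd <- hydrated_volume(geometry)
  v_mix <- mix_volume(v_hyd, geometry$swelling_factor)
  dens <- site_density(recipe, geometry)

  # what the chain gives if volumes are first rounded as printed
  v_hyd_r <- round(v_hyd, 1)
  v_mix_r <- round(v_mix)
  acrylamide_molar <- 10 * recipe$acrylamide_pct / recipe$acrylamide_molar_mass
  strept_mol <- acrylamide_molar * recipe$strept_molar_ratio * v_mix_r * 1e-6
  area_um2 <- v_hyd_r * 1e9 / geometry$hydrated_thickness_um   # uL/um -> um^2
  frac_accessible <- geometry$accessible_depth_nm * 1e-3 /
    geometry$hydrated_thickness_um
  dens_rounded <- strept_mol * .N_AVOGADRO * frac_accessible / area_um2

  tibble(
    hydrated_volume_ul = v_hyd,
    mix_volume_ul = v_mix,
    site_density_um2 = dens,
    minority_density_um2 = species_density(dens, coating_fold),
    minority_density_partition_um2 = species_density(dens, coating_fold,
                                                     convention = "partition"),
    site_density_rounded_um2 = dens_rounded
  )
}
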