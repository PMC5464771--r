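#' Plateau shear storage modulus of a gap sweep
#'
#' In a parallel-plate gap sweep G' rises as the gap closes and the sample
#' is progressively loaded; the characteristic shear modulus of the sample
#' is the maximum G' over the sweep. No smoothing or plateau detection is
#' applied -- the estimator is the plain maximum.
#'
#' @param G_prime_pa Numeric vector of storage moduli, Pa.
#' @return Maximum G', Pa.
#' @export
plateau_shear_modulus <- function(G_prime_pa) {
  if (length(G_prime_pa) == 0L) abort("empty sweep")
  if (any(G_prime_pa < 0)) abort("G' must be non-negative")
  max(G_prime_pa)
}

#' Convert shear storage modulus to Young's modulus
#'
#' For an isotropic elastic material, E = 2 (1 + nu) G'. Polyacrylamide is
#' taken as nearly incompressible with nu = 0.45, giving a conversion
#' factor of exactly 2.9.
#'
#' @param G_prime_pa Shear storage modulus, Pa (vectorised, >= 0).
#' @param nu Poisson's ratio, in (-1, 0.5]. Default 0.45.
#' @return Young's modulus, Pa.
#' @examples
#' shear_to_young(2212)  # 6414.8 Pa
#' @export
shear_to_young <- function(G_prime_pa, nu = 0.45) {
  check_nu(nu)
  if (any(G_prime_pa < 0)) abort("G' must be non-negative")
  2 * (1 + nu) * G_prime_pa
}

#' Per-sample gel elasticity from gap sweeps
#'
#' Takes long-format sweep data (one row per gap measurement), extracts each
#' sample's plateau G' (maximum over its sweep) and converts it to a
#' Young's modulus.
#'
#' @param sweeps Data frame with columns `sample_id`, `gap_mm`,
#'   `G_prime_Pa`.
#' @param nu Poisson's ratio used in the conversion. Default 0.45.
#' @return A tibble with one row per sample: `sample_id`, `n_gaps`,
#'   `G_plateau_Pa`, `nu`, `E_Pa`.
#' @export
gel_elasticity <- function(sweeps, nu = 0.45) {
  required <- c("sample_id", "gap_mm", "G_prime_Pa")
  missing <- setdiff(required, names(sweeps))
  if (length(missing) > 0L) {
    abort(sprintf("sweep data frame is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  sweeps |>
    as_tibble() |>
    group_by(.data$sample_id) |>
    summarise(n_gaps = dplyr::n(),
              G_plateau_Pa = plateau_shear_modulus(.data$G_prime_Pa),
              .groups = "drop") |>
    mutate(nu = .env$nu,
           E_Pa = shear_to_young(.data$G_plateau_Pa, nu = .env$nu))
}

#' Summarise gel elasticity across samples
#'
#' Averages per-sample moduli of one gel formulation. Conversion is linear,
#' so converting per sample and averaging gives the same mean as converting
#' the averaged plateau; standard deviations differ by the conversion
#' factor, so both are reported.
#'
#' @param elasticity Per-sample tibble from [gel_elasticity()].
#' @return One-row tibble: `n_samples`, `G_plateau_mean_Pa`,
#'   `G_plateau_sem_Pa`, `E_mean_Pa`, `E_sem_Pa`.
#' @export
summarize_gel <- function(elasticity) {
  if (nrow(elasticity) == 0L) abort("no samples")
  sem <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
  tibble(
    n_samples = nrow(elasticity),
    G_plateau_mean_Pa = mean(elasticity$G_plateau_Pa),
    G_plateau_sem_Pa = sem(elasticity$G_plateau_Pa),
    E_mean_Pa = mean(elasticity$E_Pa),
    E_sem_Pa = sem(elasticity$E_Pa)
  )
}

#' Plot a gap sweep with its plateau
#'
#' @param sweeps Data frame with `gap_mm`, `G_prime_Pa` and optionally
#'   `sample_id`.
#' @return A ggplot object: G' against gap (gap decreasing rightwards as in
#'   a loading run), with the retained plateau as a dashed line.
#' @export
plot_gap_sweep <- function(sweeps) {
  if (!"sample_id" %in% names(sweeps)) sweeps$sample_id <- "sample"
  plateau <- sweeps |>
    group_by(.data$sample_id) |>
    summarise(G_plateau_Pa = plateau_shear_modulus(.data$G_prime_Pa),
              .groups = "drop")
  ggplot2::ggplot(sweeps, ggplot2::aes(x = .data$gap_mm, y = .data$G_prime_Pa,
                                       colour = .data$sample_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = plateau,
                        ggplot2::aes(yintercept = .data$G_plateau_Pa,
                                     colour = .data$sample_id),
                        linetype = "dashed") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "gap (mm, decreasing)", y = "G' (Pa)",
                  colour = "sample")
}
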