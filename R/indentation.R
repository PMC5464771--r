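#' Convert raw cantilever displacements to force-indentation data
#'
#' A stiffness-calibrated cantilever lowered by a base displacement D onto a
#' cell deflects by D - d, where d is the tip displacement; the elastic force
#' is F = k (D - d) and the indentation depth equals the tip displacement d
#' (cell resting on a rigid support, probe indenting from above).
#'
#' @param curves Data frame with raw columns `D_um` and `d_um` (um) and an
#'   optional `curve_id` column.
#' @param k Cantilever stiffness, nN/um.
#' @param contact_offset_um Optional contact-point offset subtracted from
#'   both displacements before conversion (curves are assumed pre-zeroed at
#'   contact by default). Points with non-positive indentation after
#'   offsetting are dropped with a message.
#' @param tol Tolerance (um) for negative deflection d > D due to noise;
#'   deflections in (-tol, 0) are clipped to 0, beyond is an error.
#' @return A tibble with columns `curve_id` (if present), `delta_um`, `F_nN`,
#'   ordered as the input.
#' @examples
#' raw_to_force_indentation(data.frame(D_um = 2, d_um = 1.5), k = 3)
#' @export
raw_to_force_indentation <- function(curves, k, contact_offset_um = 0,
                                     tol = 1e-9) {
  check_number(k, "k", min = 0, strict_min = TRUE)
  if (!all(c("D_um", "d_um") %in% names(curves))) {
    abort("raw force curves need columns D_um and d_um")
  }
  D <- curves$D_um - contact_offset_um
  d <- curves$d_um - contact_offset_um
  defl <- D - d
  if (any(defl < -tol)) abort("negative deflection: d > D beyond tolerance")
  defl <- pmax(defl, 0)
  out <- tibble(delta_um = d, F_nN = k * defl)
  if ("curve_id" %in% names(curves)) out <- tibble(curve_id = curves$curve_id, out)
  if (contact_offset_um != 0) {
    keep <- out$delta_um > 0 | (curves$D_um == 0 & curves$d_um == 0)
    if (any(!keep)) {
      inform(sprintf("dropped %d point(s) with non-positive indentation after offsetting",
                     sum(!keep)))
      out <- out[keep, ]
    }
  }
  out
}

# Hertz forward model for a rigid sphere on an incompressible-to-nu cell:
# F = (16/9) sqrt(R) E delta^(3/2); with F in nN and lengths in um the
# modulus enters in kPa (nN/um^2), hence the /1000 from Pa.
hertz_force <- function(delta_um, R_um, E_pa) {
  (16 / 9) * sqrt(R_um) * (E_pa / 1000) * delta_um^1.5
}

#' Fit the Hertz spherical-contact model to a force-indentation curve
#'
#' Fits F = (16/9) sqrt(R) E delta^(3/2) (the spherical Hertz model with the
#' probe treated as rigid and the Poisson-ratio factor absorbed for
#' nu = 0.5). The model is linear in the Young's modulus E, so the fit is
#' the closed-form least-squares slope of F against (16/9) sqrt(R)
#' delta^(3/2), constrained to E >= 0 -- deterministic and exactly the
#' least-squares optimum.
#'
#' With forces in nN and lengths in um the slope is in nN/um^2 = kPa; the
#' result is reported in Pa.
#'
#' @param curve Data frame with processed columns `delta_um` and `F_nN`
#'   (single curve; see [fit_hertz_curves()] for many curves at once).
#' @param R Probe tip radius, um.
#' @param nu_cell Cell Poisson's ratio (default 0.5, incompressible).
#' @param delta_max_um Optional upper indentation bound; points beyond it
#'   are excluded from the fit.
#' @return An object of class `hertz_fit` with elements `E_cell_pa`,
#'   `nu_cell`, `E_star_pa` (reduced modulus, rigid-probe limit),
#'   `residual_rms_nN`, `n_points`, `R_um`, `clamped`, and the fitted data.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' curve <- data.frame(delta_um = seq(0.1, 2, length.out = 20))
#' curve$F_nN <- (16 / 9) * sqrt(5.7) * 1.5 * curve$delta_um^1.5 # E = 1500 Pa
#' glance(fit_hertz(curve, R = 5.7))
#' @export
fit_hertz <- function(curve, R, nu_cell = 0.5, delta_max_um = NULL) {
  check_number(R, "R", min = 0, strict_min = TRUE)
  check_nu(nu_cell)
  if (!all(c("delta_um", "F_nN") %in% names(curve))) {
    abort("processed force curves need columns delta_um and F_nN")
  }
  keep <- curve$delta_um > 0
  if (!is.null(delta_max_um)) keep <- keep & curve$delta_um <= delta_max_um
  delta <- curve$delta_um[keep]
  F_nN <- curve$F_nN[keep]
  if (length(delta) == 0L) abort("no indentation: all points have delta <= 0")

  x <- (16 / 9) * sqrt(R) * delta^1.5   # regressor, um^2: slope is kPa
  slope_kpa <- sum(x * F_nN) / sum(x^2)
  clamped <- FALSE
  if (slope_kpa < 0) {
    warn("negative fitted modulus clamped to 0")
    slope_kpa <- 0
    clamped <- TRUE
  }
  E_pa <- 1000 * slope_kpa
  resid <- F_nN - slope_kpa * x
  structure(list(
    E_cell_pa = E_pa,
    nu_cell = nu_cell,
    E_star_pa = reduced_modulus(E_pa, nu_cell),
    residual_rms_nN = sqrt(mean(resid^2)),
    n_points = length(delta),
    R_um = R,
    clamped = clamped,
    data = tibble(delta_um = delta, F_nN = F_nN,
                  fitted_nN = slope_kpa * x)
  ), class = "hertz_fit")
}

#' Fit the Hertz model to many curves
#'
#' @param curves Data frame with `curve_id`, `delta_um`, `F_nN` columns
#'   (or no `curve_id`, treated as a single curve).
#' @inheritParams fit_hertz
#' @return A tibble with one row per curve: `curve_id` plus the [glance()]
#'   columns of each fit.
#' @export
fit_hertz_curves <- function(curves, R, nu_cell = 0.5, delta_max_um = NULL) {
  if (!"curve_id" %in% names(curves)) curves$curve_id <- 1L
  curves |>
    as_tibble() |>
    dplyr::group_split(.data$curve_id) |>
    purrr::map(function(df) {
      fit <- fit_hertz(df, R = R, nu_cell = nu_cell, delta_max_um = delta_max_um)
      dplyr::bind_cols(tibble(curve_id = df$curve_id[1]), glance(fit))
    }) |>
    purrr::list_rbind()
}

#' Reduced contact modulus of a probe-sample pair
#'
#' Combines sample and probe elasticity: 1/E* = (1 - nu_cell^2)/E_cell +
#' (1 - nu_probe^2)/E_probe. With a rigid probe (default, E_probe = Inf,
#' the glass-on-cell regime where E_cell is ~kPa and E_probe ~GPa) this
#' reduces to E* = E_cell / (1 - nu_cell^2).
#'
#' @param E_cell Sample Young's modulus, Pa (>= 0).
#' @param nu_cell Sample Poisson's ratio, in (-1, 0.5].
#' @param E_probe Probe Young's modulus, Pa; `Inf` for a rigid probe.
#' @param nu_probe Probe Poisson's ratio (ignored for a rigid probe).
#' @return Reduced modulus E*, Pa.
#' @examples
#' reduced_modulus(1500, 0.5)  # (4/3) * 1500
#' @export
reduced_modulus <- function(E_cell, nu_cell = 0.5, E_probe = Inf,
                            nu_probe = NA_real_) {
  if (any(E_cell < 0)) abort("E_cell must be non-negative")
  check_nu(nu_cell)
  if (is.infinite(E_probe)) {
    return(E_cell / (1 - nu_cell^2))
  }
  check_nu(nu_probe)
  inv <- (1 - nu_cell^2) / E_cell + (1 - nu_probe^2) / E_probe
  1 / inv
}

check_nu <- function(nu) {
  if (!is.numeric(nu) || length(nu) != 1L || is.na(nu) || nu <= -1 || nu > 0.5) {
    abort("Poisson's ratio must lie in (-1, 0.5]")
  }
  invisible(nu)
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat("Hertz spherical-contact fit\n")
  cat(sprintf("  E_cell = %.1f Pa (nu = %.2f, E* = %.1f Pa)\n",
              x$E_cell_pa, x$nu_cell, x$E_star_pa))
  cat(sprintf("  %d points, residual RMS %.3g nN%s\n", x$n_points,
              x$residual_rms_nN, if (x$clamped) " [clamped at 0]" else ""))
  invisible(x)
}

#' @rdname fit_hertz
#' @param x A `hertz_fit` object.
#' @param ... Unused.
#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble(term = "E_cell_pa", estimate = x$E_cell_pa)
}

#' @rdname fit_hertz
#' @export
glance.hertz_fit <- function(x, ...) {
  tibble(E_cell_pa = x$E_cell_pa, nu_cell = x$nu_cell,
         E_star_pa = x$E_star_pa, residual_rms_nN = x$residual_rms_nN,
         n_points = x$n_points, clamped = x$clamped)
}

#' @rdname fit_hertz
#' @param object A `hertz_fit` object.
#' @exportS3Method ggplot2::autoplot
autoplot.hertz_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$delta_um)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$F_nN), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_nN), colour = "firebrick") +
    ggplot2::labs(
      x = expression(paste("indentation ", delta, " (", mu, "m)")),
      y = "force (nN)",
      title = sprintf("Hertz fit: E = %.0f Pa", object$E_cell_pa)
    )
}
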