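#' Named simulation fixtures
#'
#' The package ships a fixture table of simulation parameter sets anchored
#' to published per-condition summary statistics (speed means, cell
#' moduli, gel plateau moduli); values that are not printed anywhere --
#' speed SDs, arrest fractions, noise levels -- are synthetic and labelled
#' as such in each fixture's `source` field.
#'
#' @param group One of `"tracks"`, `"indentation"`, `"gels"`, or `NULL`
#'   for all groups.
#' @return `sim_fixtures()`: a tibble with columns `group`, `name` and
#'   `source`. `fixture_params()`: the named parameter list of one fixture
#'   (without its `source` field).
#' @export
sim_fixtures <- function(group = NULL) {
  fx <- load_fixtures()
  if (!is.null(group)) fx <- fx[group]
  purrr::imap(fx, function(entries, grp) {
    tibble(group = grp, name = names(entries),
           source = purrr::map_chr(entries, function(e) {
             as.character(e$source %||% e$E_source %||% NA)
           }))
  }) |> purrr::list_rbind()
}

#' @rdname sim_fixtures
#' @param name Fixture name, e.g. `"icam-100kPa"` or `"hela-28kPa"`.
#' @export
fixture_params <- function(name) {
  fx <- load_fixtures()
  for (grp in names(fx)) {
    if (name %in% names(fx[[grp]])) {
      p <- fx[[grp]][[name]]
      return(p[setdiff(names(p), c("source", "E_source", "G_source"))])
    }
  }
  abort(sprintf("unknown fixture '%s'; see sim_fixtures()", name))
}

load_fixtures <- function() {
  path <- system.file("extdata", "fixtures.json", package = "cellmech")
  jsonlite::read_json(path, simplifyVector = FALSE) |>
    purrr::map(function(grp) purrr::map(grp, function(e) {
      purrr::map(e, function(v) if (is.null(v)) NA_real_ else v)
    }))
}

#' Simulate two-population cell trajectories
#'
#' Generates a cohort of 2D cell tracks with an arrested and a migrating
#' sub-population, emulating lymphocyte migration filmed at one frame every
#' `dt_s` seconds for `duration_s` seconds. Each cell is independently
#' arrested with probability `frac_arrested`. Arrested cells take isotropic
#' Gaussian jitter steps (SD `arrested_jitter_sd_um` per frame, small
#' enough that their 5-min excursion stays far below the arrest threshold).
#' Migrating cells follow a persistent random walk: the cell's mean speed
#' is drawn from a zero-truncated Gaussian (between-cell variability);
#' each step's speed from a zero-truncated Gaussian around that mean
#' (within-cell variability); the heading is updated by wrapped-Gaussian
#' turns whose spread is set by `persistence` (mean resultant length of
#' the turn distribution: 1 = straight line, 0 = uncorrelated headings).
#'
#' @param n_cells Number of cells.
#' @param frac_arrested Probability that a cell is arrested, in \[0, 1\].
#' @param speed_mean_um_min,speed_sd_um_min Mean and between-cell SD of
#'   migrating-cell speeds, um/min.
#' @param step_speed_sd_um_min Within-cell SD of per-step speeds, um/min.
#' @param arrested_jitter_sd_um Per-frame positional jitter SD of arrested
#'   cells, um.
#' @param persistence Directional correlation per step, in \[0, 1\].
#' @param dt_s Frame interval, s.
#' @param duration_s Track duration, s.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param fixture Optional fixture name (see [sim_fixtures()]); its
#'   parameters override the matching defaults.
#' @return A spots tibble: `track_id`, `time_s`, `x_um`, `y_um`, plus the
#'   ground-truth `population` column (`"arrested"`/`"migrating"`).
#' @export
simulate_tracks <- function(n_cells = 100, frac_arrested = 0,
                            speed_mean_um_min = 15.5, speed_sd_um_min = 4,
                            step_speed_sd_um_min = 3,
                            arrested_jitter_sd_um = 0.1,
                            persistence = 0.7, dt_s = 5, duration_s = 300,
                            seed = NULL, fixture = NULL) {
  if (!is.null(fixture)) {
    # fixture values fill in parameters the caller did not set explicitly
    p <- fixture_params(fixture)
    if (missing(speed_mean_um_min)) speed_mean_um_min <- p$speed_mean_um_min %||% speed_mean_um_min
    if (missing(speed_sd_um_min)) speed_sd_um_min <- p$speed_sd_um_min %||% speed_sd_um_min
    if (missing(frac_arrested)) frac_arrested <- p$frac_arrested %||% frac_arrested
    if (missing(persistence)) persistence <- p$persistence %||% persistence
    if (missing(dt_s)) dt_s <- p$dt_s %||% dt_s
    if (missing(duration_s)) duration_s <- p$duration_s %||% duration_s
  }
  check_number(n_cells, "n_cells", min = 1)
  check_number(frac_arrested, "frac_arrested", min = 0, max = 1)
  check_number(speed_mean_um_min, "speed_mean_um_min", min = 0)
  check_number(speed_sd_um_min, "speed_sd_um_min", min = 0)
  check_number(persistence, "persistence", min = 0, max = 1)
  check_number(dt_s, "dt_s", min = 0, strict_min = TRUE)
  check_number(duration_s, "duration_s", min = dt_s)

  with_seed(seed, {
    n_steps <- floor(duration_s / dt_s)
    times <- seq(0, by = dt_s, length.out = n_steps + 1)
    arrested <- runif(n_cells) < frac_arrested
    cells <- purrr::map(seq_len(n_cells), function(i) {
      if (arrested[i]) {
        dx <- rnorm(n_steps, 0, arrested_jitter_sd_um)
        dy <- rnorm(n_steps, 0, arrested_jitter_sd_um)
      } else {
        cell_speed <- rtnorm_pos(1, speed_mean_um_min, speed_sd_um_min)
        step_speed <- rtnorm_pos(n_steps, cell_speed, step_speed_sd_um_min)
        step_len <- step_speed * dt_s / 60
        turns <- if (persistence == 0) {
          runif(n_steps, -pi, pi)
        } else {
          # wrapped normal with mean resultant length = persistence
          rnorm(n_steps, 0, sqrt(-2 * log(persistence)))
        }
        heading <- runif(1, 0, 2 * pi) + cumsum(c(0, turns[-1]))
        dx <- step_len * cos(heading)
        dy <- step_len * sin(heading)
      }
      tibble(
        track_id = sprintf("cell-%04d", i),
        time_s = times,
        x_um = c(0, cumsum(dx)),
        y_um = c(0, cumsum(dy)),
        population = if (arrested[i]) "arrested" else "migrating"
      )
    })
    purrr::list_rbind(cells)
  })
}

#' Simulate raw cantilever indentation curves
#'
#' Forward-simulates the Hertz spherical-contact model and emits raw
#' (base displacement D, tip displacement d) pairs: the indentation depth
#' grid is linear in (0, `delta_max_um`\]; the force is
#' F = (16/9) sqrt(R) E delta^(3/2) times multiplicative Gaussian noise;
#' the raw pair is D = delta + F/k, d = delta, so that
#' [raw_to_force_indentation()] inverts the construction exactly at zero
#' noise.
#'
#' @param E_true_pa Ground-truth Young's modulus, Pa (>= 0).
#' @param R_um Probe tip radius, um.
#' @param k_nN_um Cantilever stiffness, nN/um.
#' @param delta_max_um Maximum indentation depth, um.
#' @param n_points Points per curve.
#' @param force_noise_cv Relative SD of the multiplicative force noise.
#' @param n_curves Number of replicate curves.
#' @param seed Integer seed.
#' @param fixture Optional fixture name, e.g. `"hela-28kPa"`.
#' @return A raw-curve tibble: `curve_id`, `D_um`, `d_um`.
#' @export
simulate_indentation <- function(E_true_pa = 1500, R_um = 5.7, k_nN_um = 3,
                                 delta_max_um = 2, n_points = 50,
                                 force_noise_cv = 0, n_curves = 1,
                                 seed = NULL, fixture = NULL) {
  if (!is.null(fixture)) {
    # fixture values fill in parameters the caller did not set explicitly
    p <- fixture_params(fixture)
    if (missing(E_true_pa)) E_true_pa <- p$E_true_pa %||% E_true_pa
    if (missing(R_um)) R_um <- p$R_um %||% R_um
    if (missing(k_nN_um)) k_nN_um <- p$k_nN_um %||% k_nN_um
    if (missing(delta_max_um)) delta_max_um <- p$delta_max_um %||% delta_max_um
    if (missing(n_points)) n_points <- p$n_points %||% n_points
    if (missing(force_noise_cv)) force_noise_cv <- p$force_noise_cv %||% force_noise_cv
  }
  check_number(E_true_pa, "E_true_pa", min = 0)
  check_number(R_um, "R_um", min = 0, strict_min = TRUE)
  check_number(k_nN_um, "k_nN_um", min = 0, strict_min = TRUE)
  check_number(delta_max_um, "delta_max_um", min = 0, strict_min = TRUE)
  check_number(n_points, "n_points", min = 1)
  check_number(force_noise_cv, "force_noise_cv", min = 0)

  with_seed(seed, {
    delta <- seq(delta_max_um / n_points, delta_max_um, length.out = n_points)
    purrr::map(seq_len(n_curves), function(i) {
      F_nN <- hertz_force(delta, R_um, E_true_pa)
      if (force_noise_cv > 0) {
        F_nN <- pmax(F_nN * (1 + rnorm(n_points, 0, force_noise_cv)), 0)
      }
      tibble(curve_id = sprintf("curve-%04d", i),
             D_um = delta + F_nN / k_nN_um,
             d_um = delta)
    }) |> purrr::list_rbind()
  })
}

#' Simulate a rheometer gap sweep
#'
#' Emulates a parallel-plate loading run: as the gap between the plates is
#' decreased the sample is progressively loaded and G' rises along a
#' saturating curve, reaching the true plateau at the smallest gap;
#' additive Gaussian noise (clipped at zero) is superposed.
#'
#' @param G_plateau_pa Ground-truth plateau storage modulus, Pa (> 0).
#' @param n_gaps Number of gap settings.
#' @param loading_shape Steepness of the saturating loading curve
#'   (dimensionless; larger = earlier saturation).
#' @param noise_sd_pa Additive noise SD, Pa.
#' @param gap_range_mm Length-2 vector: smallest and largest gap, mm.
#' @param sample_id Sample label for the output.
#' @param seed Integer seed.
#' @return A sweep tibble in measurement order (decreasing gap):
#'   `sample_id`, `gap_mm`, `G_prime_Pa`.
#' @export
simulate_gap_sweep <- function(G_plateau_pa = 2212, n_gaps = 20,
                               loading_shape = 5, noise_sd_pa = 0,
                               gap_range_mm = c(0.8, 1.2),
                               sample_id = "sim-1", seed = NULL) {
  check_number(G_plateau_pa, "G_plateau_pa", min = 0, strict_min = TRUE)
  check_number(n_gaps, "n_gaps", min = 1)
  check_number(loading_shape, "loading_shape", min = 0, strict_min = TRUE)
  check_number(noise_sd_pa, "noise_sd_pa", min = 0)
  with_seed(seed, {
    gaps <- seq(max(gap_range_mm), min(gap_range_mm), length.out = n_gaps)
    s <- (max(gaps) - gaps) / (max(gaps) - min(gaps))   # 0 -> 1 as gap closes
    G <- G_plateau_pa * (1 - exp(-loading_shape * s)) / (1 - exp(-loading_shape))
    if (noise_sd_pa > 0) G <- pmax(G + rnorm(n_gaps, 0, noise_sd_pa), 0)
    tibble(sample_id = sample_id, gap_mm = gaps, G_prime_Pa = G)
  })
}
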