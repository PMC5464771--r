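test_that("raw displacement pairs convert to force-indentation by F = k (D - d)", {
  out <- raw_to_force_indentation(
    data.frame(D_um = c(2, 0, 1), d_um = c(1.5, 0, 1)), k = 3
  )
  expect_equal(out$delta_um, c(1.5, 0, 1))
  expect_equal(out$F_nN, c(1.5, 0, 0))
})

test_that("negative deflection beyond tolerance is an error", {
  expect_error(raw_to_force_indentation(data.frame(D_um = 1, d_um = 1.2), k = 3),
               "negative deflection")
  # within tolerance it is clipped to zero force
  ok <- raw_to_force_indentation(data.frame(D_um = 1, d_um = 1 + 1e-12), k = 3)
  expect_equal(ok$F_nN, 0)
})

test_that("noiseless forward-model curves refit to the generating modulus at machine precision", {
  for (E in c(500, 1500, 28000)) {
    fit <- fit_hertz(hertz_curve(E), R = 5.7)
    expect_equal(fit$E_cell_pa, E, tolerance = 1e-12)
    expect_lt(fit$residual_rms_nN, 1e-12)
  }
})

test_that("single-point fit matches the closed-form inversion", {
  # E = 9 F / (16 sqrt(R) delta^{3/2}); F = 1 nN, delta = 1 um, R = 5.7 um
  fit <- fit_hertz(data.frame(delta_um = 1, F_nN = 1), R = 5.7)
  expect_equal(fit$E_cell_pa, 9000 / (16 * sqrt(5.7)))
  expect_equal(fit$E_cell_pa, 235.6053, tolerance = 1e-6)
})

test_that("degenerate curves are handled: zero force, zero indentation, negative slope", {
  zero <- data.frame(delta_um = seq(0.1, 1, 0.1), F_nN = 0)
  expect_equal(fit_hertz(zero, R = 5.7)$E_cell_pa, 0)
  expect_error(fit_hertz(data.frame(delta_um = c(0, 0), F_nN = c(1, 2)), R = 5.7),
               "no indentation")
  neg <- data.frame(delta_um = seq(0.1, 1, 0.1), F_nN = -1)
  expect_warning(fit_neg <- fit_hertz(neg, R = 5.7), "clamped")
  expect_equal(fit_neg$E_cell_pa, 0)
})

test_that("fitted modulus scales homogeneously in force and length", {
  curve <- hertz_curve(1500)
  base <- fit_hertz(curve, R = 5.7)$E_cell_pa
  # F -> cF scales E by c
  scaled_F <- curve
  scaled_F$F_nN <- 2.5 * scaled_F$F_nN
  expect_equal(fit_hertz(scaled_F, R = 5.7)$E_cell_pa, 2.5 * base)
  # lengths -> c * lengths (R and delta) scales E by c^{-1/2} * c^{-3/2} = c^{-2}
  scaled_L <- curve
  scaled_L$delta_um <- 2 * scaled_L$delta_um
  expect_equal(fit_hertz(scaled_L, R = 2 * 5.7)$E_cell_pa, base / 4)
})

test_that("reduced modulus covers the rigid-probe limit and the two-material formula", {
  expect_equal(reduced_modulus(1500, 0.5), 2000)          # (4/3) E
  expect_equal(reduced_modulus(0, 0.5), 0)
  # kPa cell against GPa probe: indistinguishable from a rigid probe
  full <- reduced_modulus(1000, 0.5, E_probe = 1e9, nu_probe = 0.2)
  rigid <- reduced_modulus(1000, 0.5)
  expect_equal(full, rigid, tolerance = 1e-4)
  expect_error(reduced_modulus(1000, 0.6), "Poisson")
  expect_error(reduced_modulus(1000, -1), "Poisson")
})

test_that("fit of noisy replicates is unbiased (multiplicative force noise)", {
  E_true <- 1500
  fits <- purrr::map_dbl(1:200, function(i) {
    curve <- simulate_indentation(E_true_pa = E_true, force_noise_cv = 0.05,
                                  seed = 5000 + i)
    proc <- raw_to_force_indentation(curve, k = 3)
    fit_hertz(proc, R = 5.7)$E_cell_pa
  })
  se <- sd(fits) / sqrt(length(fits))
  expect_lt(abs(mean(fits) - E_true), 3 * se)
})

test_that("raw-to-processed-to-fit pipeline recovers the generating modulus end to end", {
  raw <- simulate_indentation(E_true_pa = 2400, seed = 9)
  fit <- fit_hertz(raw_to_force_indentation(raw, k = 3), R = 5.7)
  expect_equal(fit$E_cell_pa, 2400, tolerance = 1e-12)
})

test_that("hertz_fit supports tidy, glance and multi-curve fitting", {
  fit <- fit_hertz(hertz_curve(1500), R = 5.7)
  expect_equal(tidy(fit)$estimate, 1500)
  g <- glance(fit)
  expect_named(g, c("E_cell_pa", "nu_cell", "E_star_pa", "residual_rms_nN",
                    "n_points", "clamped"))
  expect_equal(g$E_star_pa, 2000)

  raw <- simulate_indentation(E_true_pa = 1500, n_curves = 3, seed = 2)
  fits <- fit_hertz_curves(raw_to_force_indentation(raw, k = 3), R = 5.7)
  expect_equal(nrow(fits), 3L)
  expect_equal(fits$E_cell_pa, rep(1500, 3), tolerance = 1e-9)
})
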