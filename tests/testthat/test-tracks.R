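test_that("instantaneous speeds match hand arithmetic", {
  spots <- tibble::tibble(track_id = "a", time_s = c(0, 5),
                          x_um = c(0, 3), y_um = c(0, 4))
  expect_equal(instantaneous_speeds(spots)$speed_um_min, 60)

  spots2 <- tibble::tibble(track_id = "b", time_s = c(0, 5, 10),
                           x_um = c(0, 1, 1), y_um = 0)
  expect_equal(instantaneous_speeds(spots2)$speed_um_min, c(12, 0))

  still <- tibble::tibble(track_id = "c", time_s = seq(0, 45, 5),
                          x_um = 2, y_um = -3)
  expect_equal(instantaneous_speeds(still)$speed_um_min, rep(0, 9))
})

test_that("single-point tracks are rejected for speeds", {
  one <- tibble::tibble(track_id = "a", time_s = 0, x_um = 0, y_um = 0)
  expect_error(instantaneous_speeds(one), "too short")
})

test_that("max excursion is the maximum pairwise distance, not displacement or path length", {
  expect_equal(max_excursion(c(0, 3, 0), c(0, 4, 0)), 5)   # net displacement 0
  expect_equal(max_excursion(c(0, 2, 7, 4), c(0, 0, 0, 0)), 7) # path length 12
  expect_equal(max_excursion(0, 0), 0)
})

test_that("max excursion equals the brute-force pairwise oracle on random tracks", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:50, 1)
    tr <- random_track(n)
    expect_equal(max_excursion(tr$x_um, tr$y_um),
                 brute_max_excursion(tr$x_um, tr$y_um))
  }
})

test_that("max excursion is at least the net displacement, with equality on straight monotone tracks", {
  set.seed(7)
  for (i in 1:20) {
    tr <- random_track(sample(2:30, 1))
    net <- sqrt(diff(range(tr$x_um[c(1, nrow(tr))]))^2 +
                  (tr$y_um[nrow(tr)] - tr$y_um[1])^2)
    expect_gte(max_excursion(tr$x_um, tr$y_um),
               sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
                      (tr$y_um[nrow(tr)] - tr$y_um[1])^2))
  }
  st <- straight_track(25)
  expect_equal(max_excursion(st$x_um, st$y_um), 25)
})

test_that("metrics are invariant to rigid motions and scale with dilations", {
  set.seed(11)
  tr <- random_track(30)
  base_exc <- max_excursion(tr$x_um, tr$y_um)
  base_speed <- mean(step_speeds(tr$time_s, tr$x_um, tr$y_um))

  # translation
  expect_equal(max_excursion(tr$x_um + 13, tr$y_um - 5), base_exc)
  # rotation by 37 degrees
  th <- 37 * pi / 180
  xr <- tr$x_um * cos(th) - tr$y_um * sin(th)
  yr <- tr$x_um * sin(th) + tr$y_um * cos(th)
  expect_equal(max_excursion(xr, yr), base_exc)
  expect_equal(mean(step_speeds(tr$time_s, xr, yr)), base_speed)
  # dilation by c scales both metrics by c
  expect_equal(max_excursion(3 * tr$x_um, 3 * tr$y_um), 3 * base_exc)
  expect_equal(mean(step_speeds(tr$time_s, 3 * tr$x_um, 3 * tr$y_um)),
               3 * base_speed)
})

test_that("arrest boundary is strict and the threshold scales with duration", {
  expect_true(classify_arrest(9.9, 300))
  expect_false(classify_arrest(10, 300))
  expect_true(classify_arrest(4.9, 150))    # scaled threshold: 5 um per 2.5 min
  expect_false(classify_arrest(5.1, 150))
  expect_true(classify_arrest(19.9, 600))   # longer window scales up too
})

test_that("distance rule at 10 um / 300 s is the 2 um/min rate rule on any window", {
  set.seed(3)
  for (i in 1:20) {
    dur <- runif(1, 60, 600)
    exc <- runif(1, 0, 25)
    expect_identical(classify_arrest(exc, dur),
                     (exc / (dur / 60)) < 2)   # rate in um/min
  }
})

test_that("cohort summary aggregates velocity over migrating tracks only", {
  arrested <- purrr::map(1:3, \(i) {
    tr <- straight_track(3, id = paste0("a", i))
    tr
  }) |> purrr::list_rbind()
  migrating <- straight_track(60, id = "m1")  # 60 um / 5 min = 12 um/min
  summ <- summarize_cohort(dplyr::bind_rows(arrested, migrating))
  expect_equal(summ$n_tracks, 4L)
  expect_equal(summ$percent_arrested, 75)
  expect_equal(summ$velocity_mean, 12)
  expect_equal(summ$n_velocity_tracks, 1L)

  all_arr <- summarize_cohort(arrested)
  expect_equal(all_arr$percent_arrested, 100)
  expect_false(all_arr$velocity_defined)
  expect_true(is.na(all_arr$velocity_mean))

  # velocity_population = "all" includes arrested tracks
  summ_all <- summarize_cohort(dplyr::bind_rows(arrested, migrating),
                               velocity_population = "all")
  expect_equal(summ_all$n_velocity_tracks, 4L)
  expect_lt(summ_all$velocity_mean, summ$velocity_mean)
})

test_that("short tracks are excluded from velocity statistics with a message", {
  two_pt <- tibble::tibble(track_id = "s", time_s = c(0, 5),
                           x_um = c(0, 10), y_um = 0)
  full <- straight_track(60, id = "m")
  expect_message(
    summ <- summarize_cohort(dplyr::bind_rows(two_pt, full)),
    "excluded"
  )
  expect_equal(summ$n_velocity_tracks, 1L)
  expect_equal(summ$n_tracks, 2L)
})

test_that("cohort arrest fraction tracks the generating fraction", {
  spots <- simulate_tracks(n_cells = 200, frac_arrested = 0.3, seed = 101)
  summ <- summarize_cohort(spots)
  se <- sqrt(0.3 * 0.7 / 200)
  expect_lt(abs(summ$percent_arrested / 100 - 0.3), 3 * se)
})

test_that("spots validation flags missing columns, duplicates and irregular sampling", {
  expect_error(track_metrics(tibble::tibble(track_id = "a", x_um = 1)),
               "missing column")
  dup <- tibble::tibble(track_id = "a", time_s = c(0, 0), x_um = 1:2, y_um = 0)
  expect_error(track_metrics(dup), "duplicate")
  uneven <- tibble::tibble(track_id = "a", time_s = c(0, 5, 30),
                           x_um = 1:3, y_um = 0)
  expect_warning(track_metrics(uneven), "non-uniform")
})
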