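# Synthetic plate rendering and its closed-form ground truth.

test_that("mixing functions follow their closed forms", {
  t <- c(0, 5, 10, 50)
  w <- well_kinetic_spec("exponential_decay", c(255, 0, 0), c(0, 0, 0),
                         rate = 0.1, lag = 5)
  expect_equal(mixing_value(w, t), exp(-0.1 * pmax(0, t - 5)))
  wl <- well_kinetic_spec("logistic", c(255, 0, 0), c(0, 0, 0),
                          midpoint = 10, steepness = 0.5)
  expect_equal(mixing_value(wl, 10), 0.5)
  ws <- well_kinetic_spec("step", c(255, 0, 0), c(0, 0, 0), step_time = 7)
  expect_equal(mixing_value(ws, t), c(1, 1, 0, 0))
  wt <- well_kinetic_spec("turbidity_clear", c(255, 0, 0), c(0, 0, 0),
                          rate = 0.2, amplitude = 0.4)
  expect_equal(mixing_value(wt, 0), 0.4)
  expect_equal(well_colour(w, 0), matrix(c(255, 0, 0), 1))
})

test_that("constant noise-free wells render identical frames; seeds fix noise", {
  w <- list(well_kinetic_spec("constant", c(120, 40, 200)))
  spec <- demo_plate(w, fps = 2, duration = 2)
  fs <- render_plate(spec)
  expect_equal(fs$n_frames, 5L)
  expect_identical(fs$frames[[1]], fs$frames[[5]])
  specn <- demo_plate(w, fps = 2, duration = 2, noise_sd = 4, seed = 99)
  a <- render_plate(specn); b <- render_plate(specn)
  expect_identical(a$frames, b$frames)                  # same seed, bit-identical
  specm <- demo_plate(w, fps = 2, duration = 2, noise_sd = 4, seed = 100)
  expect_false(identical(render_plate(specm)$frames[[1]], a$frames[[1]]))
})

test_that("noise-free well means equal the programmed trajectory", {
  w <- well_kinetic_spec("exponential_decay", c(200, 20, 60), c(240, 240, 240),
                         rate = 0.05)
  spec <- demo_plate(list(w), fps = 1, duration = 20)
  tr_exact <- extract_traces(plate_frame_source(spec, quantise = FALSE), spec$masks)
  want <- well_colour(w, tr_exact$time_s)
  expect_equal(cbind(tr_exact$R, tr_exact$G, tr_exact$B), unname(want),
               tolerance = 1e-12)
  tr_q <- extract_traces(plate_frame_source(spec, quantise = TRUE), spec$masks)
  expect_lt(max(abs(tr_q$R - want[, 1])), 0.5 + 1e-9)   # rounding policy
})

test_that("streaming and in-memory rendering agree frame for frame", {
  w <- list(well_kinetic_spec("logistic", c(90, 30, 140), c(235, 235, 235),
                              midpoint = 5, steepness = 0.5))
  spec <- demo_plate(w, fps = 2, duration = 10, noise_sd = 3, seed = 42)
  fs <- render_plate(spec)
  src <- plate_frame_source(spec)
  for (i in c(1, 7, 21)) expect_identical(src$get_frame(i), fs$frames[[i]])
})

test_that("invalid plate specs are rejected", {
  g_overlap <- grid_spec(1, 2, c(10, 10), 6, 8)       # pitch < diameter
  wells <- list(A1 = well_kinetic_spec("constant", c(1, 1, 1)),
                A2 = well_kinetic_spec("constant", c(1, 1, 1)))
  expect_error(plate_video_spec(g_overlap, wells, 30, 40, duration = 1), "overlap")
  g_out <- grid_spec(1, 2, c(3, 10), 20, 8)
  expect_error(plate_video_spec(g_out, wells, 30, 40, duration = 1), "beyond")
  expect_error(plate_video_spec(grid_spec(1, 1, c(10, 10), 1, 8),
                                list(), 30, 40, duration = 1), "missing kinetic")
  expect_error(well_kinetic_spec("logistic", c(1, 1, 1), c(2, 2, 2)), "midpoint")
})

test_that("analytic ground truth honours the closed forms", {
  step <- well_kinetic_spec("step", c(255, 255, 255), c(0, 0, 0), step_time = 10)
  const <- well_kinetic_spec("constant", c(50, 60, 70))
  spec <- demo_plate(list(step, const), fps = 1, duration = 40)
  truth <- analytic_summary(spec)
  # step: dE jumps to 100 at t = 10, so AUC = 100 * (duration - step_time)
  expect_lt(abs(truth$auc[1] - 100 * 30), 0.5)   # dense-grid trapezoid at the jump
  expect_true(is.na(truth$endpoint_s[2]))
  expect_true(is.na(truth$induction_s[2]))
  expect_equal(truth$auc[2], 0)
  logi <- well_kinetic_spec("logistic", c(90, 30, 140), c(235, 235, 235),
                            midpoint = 100, steepness = 0.05)
  spec2 <- demo_plate(list(logi), fps = 1, duration = 300)
  truth2 <- analytic_summary(spec2)
  # the contrast profile's rate peak sits near the midpoint; the small shift
  # is the nonlinear RGB -> Lab image of the logistic trajectory
  expect_lt(abs(truth2$induction_s - 100), 3)
})

test_that("measured delta-E tracks the closed form within quantisation", {
  w <- list(well_kinetic_spec("exponential_decay", c(90, 30, 140), c(235, 235, 235),
                              rate = 0.02))
  spec <- demo_plate(w, fps = 2, duration = 200)
  tr <- extract_traces(plate_frame_source(spec, quantise = TRUE), spec$masks)
  lab <- srgb_to_lab(well_colour(w[[1]], tr$time_s))
  de_true <- delta_e(lab, lab[1, , drop = FALSE])
  expect_lt(max(abs(tr$deltaE - de_true)), 1.0)
})

test_that("noisy quantised endpoints stay within 5% of the analytic values", {
  grid <- grid_spec(1, 2, origin = c(20, 20), pitch = 40, diameter = 30)
  wells <- list(
    A1 = well_kinetic_spec("logistic", c(90, 30, 140), c(235, 235, 235),
                           midpoint = 200, steepness = 0.08),
    A2 = well_kinetic_spec("exponential_decay", c(90, 30, 140), c(235, 235, 235),
                           rate = 0.05, lag = 150))
  cfg <- endpoint_config(smoothing_window = 101)   # 20 s at 5 fps, noise-matched
  truth <- NULL
  res <- sapply(1:20, function(s) {
    spec <- plate_video_spec(grid, wells, 56, 82, fps = 5, duration = 400,
                             noise_sd = 5, seed = s)
    if (is.null(truth)) truth <<- analytic_summary(spec)
    tr <- extract_traces(plate_frame_source(spec, quantise = TRUE), spec$masks)
    summarise_kinetics(tr, cfg)$endpoint_s
  })
  expect_false(anyNA(res))
  for (k in 1:2) {
    expect_true(all(abs(res[k, ] - truth$endpoint_s[k]) / truth$endpoint_s[k] < 0.05))
  }
})
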