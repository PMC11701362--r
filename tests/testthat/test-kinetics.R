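# Trace extraction, smoothing/differentiation, plateau end points,
# induction times and AUC.

test_that("constant video yields identically zero delta-E", {
  fs <- frame_seq(replicate(6, make_frame(12, 20, c(80, 120, 160)),
                            simplify = FALSE), 5)
  masks <- build_masks(grid_spec(1, 2, c(4, 5), 10, 5), 12, 20)
  tr <- extract_traces(fs, masks)
  expect_equal(tr$deltaE, rep(0, 12))
  expect_equal(unique(tr$R), 80)
})

test_that("each ROI reports its own well colour exactly", {
  fr <- make_frame(12, 20, c(0, 0, 0))
  m <- build_masks(grid_spec(1, 2, c(4, 5), 10, 5), 12, 20)
  for (k in 1:2) {
    colr <- list(c(200, 10, 40), c(15, 220, 100))[[k]]
    for (ch in 1:3) {
      sl <- fr[, , ch]; sl[m[[k]]$idx] <- colr[ch]; fr[, , ch] <- sl
    }
  }
  tr <- extract_traces(frame_seq(list(fr, fr), 1), m)
  t1 <- split_traces(tr)
  expect_equal(unique(t1$A1$R), 200); expect_equal(unique(t1$A1$B), 40)
  expect_equal(unique(t1$A2$G), 220)
  expect_equal(tr$deltaE, rep(0, 4))
})

test_that("a white-to-black step produces a delta-E step of exactly 100", {
  k <- 4L
  frames <- c(replicate(k - 1, make_frame(8, 8, c(255, 255, 255)), simplify = FALSE),
              replicate(3, make_frame(8, 8, c(0, 0, 0)), simplify = FALSE))
  masks <- build_masks(grid_spec(1, 1, c(3, 3), 1, 4), 8, 8)
  tr <- extract_traces(frame_seq(frames, 2), masks)
  expect_equal(tr$deltaE, c(rep(0, k - 1), rep(100, 3)))
})

test_that("delta-E is invariant to pixel ordering within a mask", {
  set.seed(3)
  frames <- replicate(4, array(sample(0:255, 10 * 10 * 3, TRUE), c(10, 10, 3)),
                      simplify = FALSE)
  masks <- build_masks(grid_spec(1, 1, c(5, 5), 1, 6), 10, 10)
  tr1 <- extract_traces(frame_seq(frames, 1), masks)
  perm <- sample(nrow(masks[[1]]$pixels))
  masks[[1]]$pixels <- masks[[1]]$pixels[perm, ]
  masks[[1]]$idx <- masks[[1]]$idx[perm]
  tr2 <- extract_traces(frame_seq(frames, 1), masks)
  expect_equal(tr1$deltaE, tr2$deltaE)
})

test_that("moving-average smoothing honours its contracts", {
  expect_equal(smooth_series(rep(4, 10), 5), rep(4, 10))      # constants fixed
  x <- rnorm(10)
  expect_equal(smooth_series(x, 1), x)                        # window 1 = identity
  ramp <- 2 * (0:19) + 3
  sm <- smooth_series(ramp, 7)
  expect_equal(sm[4:17], ramp[4:17])                          # affine interior
  expect_error(smooth_series(ramp, 4), "odd")
  expect_error(smooth_series(1:3, 5), "length")
})

test_that("series_gradient reproduces finite-difference identities", {
  t <- 0:10
  expect_equal(series_gradient(2 * t, t), rep(2, 11))
  expect_equal(series_gradient(rep(5, 11), t), rep(0, 11))
  g <- series_gradient(t^2, t)
  expect_equal(g[2:10], 2 * t[2:10])                          # exact for quadratics
  expect_error(series_gradient(1, 1), "at least 2")
})

test_that("endpoint detection requires activation, crossing and persistence", {
  cfg <- endpoint_config(smoothing_window = 5, persistence_s = 3)
  t <- seq(0, 60, by = 0.5)
  expect_true(is.na(detect_endpoint(t, rep(0, length(t)), cfg)))   # never activates
  expect_true(is.na(detect_endpoint(t, 2 * t, cfg)))               # never plateaus
  # rises at 1 dE/s for 20 s then flat: plateau starts near t = 20
  y <- pmin(t, 20)
  ep <- detect_endpoint(t, y, cfg)
  expect_lt(abs(ep - 20), 3)   # resolution limited by the smoothing window
  expect_error(detect_endpoint(t[1:3], y[1:3], endpoint_config()), "smoothing window")
})

test_that("endpoint matches the closed-form crossing on a programmed logistic well", {
  w <- well_kinetic_spec("logistic", c(90, 30, 140), c(235, 235, 235),
                         midpoint = 100, steepness = 0.05)
  spec <- demo_plate(list(w), fps = 5, duration = 300)
  tr <- extract_traces(plate_frame_source(spec, quantise = FALSE), spec$masks)
  cfg <- endpoint_config()
  ep <- detect_endpoint(tr$time_s, tr$deltaE, cfg)
  truth <- analytic_summary(spec, cfg)
  expect_lt(abs(ep - truth$endpoint_s), 2 / 5)                 # within 2 frames
})

test_that("doubling the sampling rate moves the endpoint by < one coarse interval", {
  w <- well_kinetic_spec("logistic", c(90, 30, 140), c(235, 235, 235),
                         midpoint = 100, steepness = 0.05)
  eps <- sapply(c(5, 10), function(fps) {
    spec <- demo_plate(list(w), fps = fps, duration = 300)
    tr <- extract_traces(plate_frame_source(spec, quantise = FALSE), spec$masks)
    # same smoothing timescale (1 s) at both rates
    detect_endpoint(tr$time_s, tr$deltaE,
                    endpoint_config(smoothing_window = fps * 2 + 1))
  })
  expect_lt(abs(eps[2] - eps[1]), 1 / 5)
})

test_that("induction time finds the maximum-rate point", {
  cfg <- endpoint_config(smoothing_window = 5)
  t <- seq(0, 100, by = 0.5)
  expect_true(is.na(induction_time(t, rep(7, length(t)), cfg)))
  y <- c(rep(0, 100), rep(40, length(t) - 100))               # step at t = 50
  expect_lt(abs(induction_time(t, y, cfg) - 50), 1.6)         # window-limited
  # a channel that carries the programmed logistic peaks at its midpoint
  w <- well_kinetic_spec("logistic", c(90, 30, 140), c(235, 235, 235),
                         midpoint = 120, steepness = 0.06)
  spec <- demo_plate(list(w), fps = 5, duration = 300)
  tr <- extract_traces(plate_frame_source(spec, quantise = FALSE), spec$masks)
  ind_r <- induction_time(tr$time_s, tr$R, endpoint_config())
  expect_lt(abs(ind_r - 120), 2 / 5)               # within 2 frames
  # the contrast profile is a nonlinear image of the trajectory, so its rate
  # peak sits near, not exactly at, the programmed midpoint
  ind_de <- induction_time(tr$time_s, tr$deltaE, endpoint_config())
  expect_lt(abs(ind_de - 120), 5)
  # threshold mode reports the first fast-change time instead
  thr <- induction_time(tr$time_s, tr$deltaE, endpoint_config(),
                        mode = "threshold", threshold = 0.05)
  expect_lt(thr, ind_de)
})

test_that("AUC reproduces triangle and rectangle closed forms", {
  t10 <- seq(0, 10, by = 0.1)
  expect_equal(trace_auc(t10, rep(0, length(t10))), 0)
  expect_equal(trace_auc(t10, t10), 50)                       # triangle 0..10
  t20 <- seq(0, 20, by = 0.25)
  expect_equal(trace_auc(t20, rep(5, length(t20))), 100)      # rectangle
  expect_error(trace_auc(1, 1), "at least 2")
})

test_that("summarise_kinetics assembles per-ROI rows with NA semantics", {
  wells <- list(well_kinetic_spec("logistic", c(90, 30, 140), c(235, 235, 235),
                                  midpoint = 80, steepness = 0.06),
                well_kinetic_spec("constant", c(90, 30, 140)))
  spec <- demo_plate(wells, fps = 5, duration = 300)
  tr <- extract_traces(plate_frame_source(spec, quantise = FALSE), spec$masks)
  smry <- summarise_kinetics(tr)
  expect_identical(smry$label, c("A1", "A2"))
  expect_true(smry$complete[1]); expect_false(smry$complete[2])
  expect_true(is.na(smry$endpoint_s[2]) && is.na(smry$induction_s[2]))
  expect_gte(smry$endpoint_s[1], smry$induction_s[1])
  expect_equal(smry$auc[2], 0)
  expect_error(summarise_kinetics(tr, induction_channel = "bogus"), "unknown channel")
  # NA endpoints serialise as empty CSV fields
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary(smry, path)
  expect_match(readLines(path)[3], ",,")
})
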