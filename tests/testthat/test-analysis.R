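make_fs <- function(V, dx = 0.25, times = NULL) {
  if (is.null(times)) times <- (seq_len(dim(V)[3]) - 1) * 2
  eadwave:::new_frame_series(times = times, V = V, dx = dx)
}

test_that("pseudo-ECG is zero for uniform fields and symmetric dipoles", {
  V <- array(-50, c(15, 15, 3))
  ecg <- pseudo_ecg(make_fs(V))
  expect_equal(ecg$ecg, rep(0, 3), tolerance = 1e-14)
  # two equal-magnitude opposite dipoles mirrored about the electrode axis
  # (V antisymmetric under x -> 17 - x, so the contributions cancel)
  f <- matrix(0, 16, 16)
  f[4, ] <- 30; f[5, ] <- -30          # dipole A
  f[12, ] <- 30; f[13, ] <- -30        # opposite dipole B
  V2 <- array(f, c(16, 16, 1))
  ecg2 <- pseudo_ecg(make_fs(V2))      # electrode centred between them
  expect_equal(ecg2$ecg, 0, tolerance = 1e-12)
})

test_that("pseudo-ECG equals the brute-force double-loop oracle", {
  set.seed(7)
  for (i in 1:5) {
    v <- matrix(rnorm(400, -60, 25), 20, 20)
    fs <- make_fs(array(v, c(20, 20, 1)))
    el <- c(runif(1, 0, 5), runif(1, 0, 5), runif(1, 1, 4))
    got <- pseudo_ecg(fs, electrode = el)$ecg
    want <- oracle_ecg_frame(v, 0.25, el)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("a passing plane wave gives a biphasic ECG deflection", {
  m <- make_movie("plane_movie", nx = 30, ny = 30, duration = 1500,
                  frame_interval = 4, freq = 2)
  ecg <- pseudo_ecg(m)
  expect_gt(max(ecg$ecg), 0)
  expect_lt(min(ecg$ecg), 0)
})

test_that("the electrode may not sit on a tissue node", {
  fs <- make_fs(array(0, c(10, 10, 1)))
  expect_error(pseudo_ecg(fs, electrode = c(0.25, 0.25, 0)), "singular")
})

test_that("spectra recover pure tones and their spatial mixtures", {
  nx <- 20; nt <- 2001
  times <- (seq_len(nt) - 1) * 2
  V <- array(0, c(nx, nx, nt))
  for (k in seq_len(nt)) V[, , k] <- sin(2 * pi * 6 * times[k] / 1000)
  sp <- mean_power_spectrum(make_fs(V, times = times), n_points = 100)
  expect_equal(dominant_frequency(sp), 6, tolerance = attr(sp, "df"))
  # 2 Hz and 3 Hz tones in disjoint halves -> two peaks
  for (k in seq_len(nt)) {
    V[1:10, , k] <- sin(2 * pi * 2 * times[k] / 1000)
    V[11:20, , k] <- sin(2 * pi * 3 * times[k] / 1000)
  }
  sp2 <- mean_power_spectrum(make_fs(V, times = times), n_points = 400)
  pk <- spectral_peaks(sp2)
  expect_setequal(round(sort(utils::head(pk$freq, 2)), 1), c(2, 3))
})

test_that("white-noise movies yield no spectral peak", {
  for (seed in c(1, 7, 23)) {
    m <- make_movie("noise_movie", nx = 16, ny = 16, duration = 4000,
                    frame_interval = 4, seed = seed)
    sp <- mean_power_spectrum(m, n_points = 64)
    expect_equal(nrow(spectral_peaks(sp)), 0)
  }
})

test_that("peak frequencies do not depend on the sublattice phase", {
  m <- make_movie("phase_osc_movie", freq = 5)
  f0 <- dominant_frequency(mean_power_spectrum(m, n_points = 100, offset = 0))
  f1 <- dominant_frequency(mean_power_spectrum(m, n_points = 100, offset = 1))
  expect_equal(f0, f1)
})

test_that("a too-short record raises a resolution error", {
  V <- array(rnorm(10 * 10 * 100), c(10, 10, 100))
  expect_error(mean_power_spectrum(make_fs(V)), "resolves only")
})

test_that("interbeat intervals recover the period of a tone", {
  m <- make_movie("phase_osc_movie", freq = 6, base = -25, amp = 20)
  ibi <- interbeat_intervals(m)
  expect_gt(nrow(ibi$beats), 0)
  expect_equal(median(ibi$beats$interval), 1000 / 6, tolerance = 0.05)
})

test_that("alternating large and small beats form two interval clusters", {
  # one node, amplitude-alternating pulse train
  nt <- 4001
  times <- seq_len(nt) - 1
  v <- rep(-80, nt)
  big <- seq(100, 3900, by = 400)
  for (i in seq_along(big)) {
    amp <- if (i %% 2 == 0) 110 else 60
    idx <- big[i] + 0:40
    v[idx] <- -80 + amp * sin(pi * (0:40) / 40)
  }
  V <- array(rep(v, each = 1), c(1, 1, nt))
  fs <- make_fs(V, times = times)
  cfg <- pattern_config(stride = 1)
  ibi <- interbeat_intervals(fs, cfg, amplitude_bands = c(0, 80, 140))
  expect_equal(nrow(ibi$beats), length(big) - 1)
  expect_equal(length(unique(ibi$histogram$amp_band)), 2)
})

test_that("a single-beat trace yields an empty interval list", {
  m <- make_movie("plane_movie", duration = 3200)
  ibi <- interbeat_intervals(m)
  expect_equal(nrow(ibi$beats), 0)
})

test_that("sustainment distinguishes a single passage from a persistent pattern", {
  plane <- make_movie("plane_movie")
  expect_false(sustained_activity(plane, t_after_last_stim = 1000))
  spiral <- make_movie("spiral_movie")
  expect_true(sustained_activity(spiral, t_after_last_stim = 1000))
  expect_error(sustained_activity(plane, t_after_last_stim = 10000),
               "before the sustainment deadline")
})

test_that("line profiles show a straight front for a plane wave", {
  m <- make_movie("plane_movie", freq = 2)
  lp <- line_profile(m, row = 24)
  expect_equal(dim(lp), c(48, dim(m$V)[3]))
  # arrival time grows linearly with x
  arrivals <- apply(lp, 1, function(v) attr(lp, "times")[which(v > -30)[1]])
  fit <- lm(arrivals ~ seq_along(arrivals))
  expect_gt(summary(fit)$r.squared, 0.99)
  # uniform field -> constant matrix
  u <- make_fs(array(-70, c(12, 12, 5)))
  expect_equal(as.vector(line_profile(u, column = 3)),
               rep(-70, 12 * 5))
  expect_error(line_profile(m, row = 99), "out of range")
  expect_error(line_profile(m, row = 1, column = 1), "exactly one")
})

test_that("wave attribution follows the floor/availability rule exactly", {
  na_m <- make_movie("plane_movie", mediator = "Na", duration = 3200)
  att <- attribute_waves(na_m, t_min = 0)
  expect_gt(nrow(att), 0)
  expect_equal(attr(att, "na_fraction"), 1)
  ca_m <- make_movie("plane_movie", mediator = "Ca", duration = 3200)
  att2 <- attribute_waves(ca_m, t_min = 0)
  expect_equal(attr(att2, "ca_fraction"), 1)
  expect_equal(attr(att, "na_fraction") + attr(att, "ca_fraction"), 1)
  # no upstrokes -> empty attribution, not an error
  quiet <- make_movie("noise_movie", noise_sd = 0.1)
  att3 <- attribute_waves(quiet, t_min = 0)
  expect_equal(nrow(att3), 0)
})

test_that("frame series round-trip through the plain-text exporter", {
  m <- make_movie("plane_movie", nx = 8, ny = 8, duration = 40,
                  frame_interval = 10)
  d <- tempfile()
  write_frames(m, d)
  m2 <- read_frames(d)
  expect_equal(m2$V, m$V, tolerance = 1e-12)
  expect_equal(m2$times, m$times)
  expect_equal(m2$dx, m$dx)
})
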