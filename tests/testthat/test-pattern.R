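test_that("the labelled fixture matrix classifies with full agreement", {
  cases <- list(
    list(kind = "plane_movie", args = list(mediator = "Na")),
    list(kind = "plane_movie", args = list(mediator = "Ca")),
    list(kind = "target_movie", args = list(mediator = "Na")),
    list(kind = "spiral_movie", args = list(n_spirals = 1, mediator = "Na")),
    list(kind = "spiral_movie", args = list(n_spirals = 2, mediator = "Na")),
    list(kind = "spiral_movie", args = list(n_spirals = 2, mediator = "Ca")),
    list(kind = "phase_osc_movie", args = list(freq = 6)))
  for (cs in cases) {
    m <- do.call(make_movie, c(list(kind = cs$kind), cs$args))
    rep <- classify_pattern(m)
    expect_equal(rep$label, m$truth$label,
                 info = paste(cs$kind, cs$args$mediator, cs$args$n_spirals))
  }
})

test_that("phase-singularity counting sees spiral cores", {
  one <- make_movie("spiral_movie", n_spirals = 1)
  ps1 <- phase_singularities(one, t_min = 1000)
  expect_true(all(ps1$count == 1))
  two <- make_movie("spiral_movie", n_spirals = 2)
  ps2 <- phase_singularities(two, t_min = 1000)
  expect_true(all(ps2$count >= 2))
  flat <- make_movie("phase_osc_movie")
  ps0 <- phase_singularities(flat, t_min = 1000)
  expect_true(all(ps0$count == 0))
})

test_that("the OSC pattern's spectrum matches its construction frequency", {
  m <- make_movie("phase_osc_movie", freq = 6)
  rep <- classify_pattern(m)
  expect_equal(rep$dominant_frequencies[1], 6,
               tolerance = 2 * attr(rep$evidence$spectrum, "df"))
})

test_that("pattern reports tidy into one-row summaries", {
  rep <- classify_pattern(make_movie("spiral_movie", n_spirals = 1))
  td <- tidy(rep)
  expect_equal(nrow(td), 1)
  expect_true(all(c("label", "sustained", "na_fraction", "dominant_freq") %in%
                  names(td)))
})

test_that("the barrier test demands a developed pattern", {
  cfg <- tissue_config(nx = 24, ny = 24, duration = 500, protocol = "none",
                       frame_interval = 4, record_gates = FALSE)
  expect_error(phase_wave_test(cfg, tissue_state_rest(24, 24), block = 8),
               "developed pattern")
})

test_that("decoupled oscillators pass the barrier test as phase waves", {
  st <- make_oscillator_state(24, 24, theta = 0.4, wavelength = 16)
  cfg <- tissue_config(nx = 24, ny = 24, D = 0, duration = 1200,
                       protocol = "none", params = regime_params("osc"),
                       frame_interval = 4, record_gates = FALSE)
  verdict <- phase_wave_test(cfg, st, block = 8, test_window = 1200)
  expect_equal(as.character(verdict), "PHASE_WAVES")
  expect_gte(attr(verdict, "active_fraction"), 0.5)
})

test_that("a diffusive wave source is confined by barriers (trigger waves)", {
  # develop target waves from a paced centre block, then impose the grid
  cfg <- tissue_config(nx = 24, ny = 24, duration = 450, protocol = "none",
                       frame_interval = 4, record_gates = FALSE)
  src <- as.integer(outer(9:16, (9:16 - 1) * 24, `+`))
  stims <- list(list(onset = 10, dur = 3, amp = 30, nodes = src),
                list(onset = 400, dur = 3, amp = 30, nodes = src))
  fs <- run_tissue(cfg, stims = stims)
  verdict <- phase_wave_test(cfg, fs$final_state, block = 8,
                             test_window = 1200)
  expect_equal(as.character(verdict), "TRIGGER_WAVES")
})
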