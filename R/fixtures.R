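#' Synthetic AP traces with known ground truth
#'
#' Piecewise-smooth analytic templates of the three AP morphologies, used to
#' exercise the classifiers without running the ionic model: an upstroke to
#' +20 mV, a decaying plateau, `k` raised-cosine EAD humps (at V above -40
#' mV), and repolarization to -86 mV; the oscillatory template never drops
#' below -60 mV.
#'
#' @param kind `"normal_ap"`, `"ead_ap"` or `"osc_ap"`.
#' @param k Number of EAD humps (only for `"ead_ap"`).
#' @param ead_height Hump height [mV].
#' @param osc_freq Oscillation frequency of the `osc_ap` template [Hz].
#' @param duration Trace length [ms] (>= 3.5 s after the stimulus so the
#'   classifier's rest window is covered).
#' @param dt Sampling interval [ms].
#' @return An `ap_trace` with the ground-truth label in `attr(, "truth")`.
#' @export
make_ap_trace <- function(kind = c("normal_ap", "ead_ap", "osc_ap"), k = 0,
                          ead_height = 20, osc_freq = 6, duration = 4000,
                          dt = 1) {
  kind <- match.arg(kind)
  if (kind != "ead_ap" && k > 0)
    stop("EAD count k only applies to kind = 'ead_ap'", call. = FALSE)
  if (kind == "ead_ap" && k < 1) k <- 1
  t <- seq(0, duration, by = dt)
  v <- rep(-86, length(t))
  t_up <- 10
  rel <- t - t_up
  up <- rel >= 0 & rel < 2
  v[up] <- -86 + (20 - -86) * rel[up] / 2

  if (kind == "osc_ap") {
    seg <- rel >= 2 & rel < 102
    v[seg] <- 20 - (20 - -15) * (rel[seg] - 2) / 100
    seg <- rel >= 102
    v[seg] <- -15 + 15 * sin(2 * pi * osc_freq * (rel[seg] - 102) / 1000)
    label <- "OSCILLATORY"
  } else {
    plateau_len <- 220 + 140 * max(k, 0)
    seg <- rel >= 2 & rel < 2 + plateau_len
    v[seg] <- 20 - (20 - -35) * (rel[seg] - 2) / plateau_len
    if (kind == "ead_ap") {
      for (j in seq_len(k)) {
        c_j <- 2 + 140 + (j - 1) * 130          # hump centres, >100 ms after upstroke
        hump <- rel >= c_j - 30 & rel <= c_j + 30
        v[hump] <- v[hump] +
          ead_height * 0.5 * (1 + cos(pi * (rel[hump] - c_j) / 30))
      }
    }
    t_rep <- 2 + plateau_len
    seg <- rel >= t_rep & rel < t_rep + 60
    v[seg] <- -35 + (-86 - -35) * (rel[seg] - t_rep) / 60
    v[rel >= t_rep + 60] <- -86
    label <- if (kind == "ead_ap") "EAD" else "NORMAL"
  }
  tr <- new_ap_trace(tibble::tibble(t = t, V = v),
                     stim = list(onsets = t_up, amp = 20, dur = 2),
                     dt = dt,
                     truth = list(kind = kind, label = label,
                                  ead_count = if (kind == "ead_ap") k else 0L))
  tr
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Synthetic 2D voltage/gate movies with known ground truth
#'
#' Analytic frame stacks emulating the morphologies the pattern analyses
#' must recognize, with gate-product channels synthesized consistently with
#' the declared Na/Ca truth:
#' \describe{
#'   \item{plane_movie}{periodic plane-wave pulse train along +x.}
#'   \item{spiral_movie}{rotating Archimedean spiral(s) of a template pulse
#'     (`n_spirals` 1 or 2: two gives counter-rotating cores, i.e. a broken
#'     multi-spiral pattern).}
#'   \item{target_movie}{concentric rings from the domain centre.}
#'   \item{phase_osc_movie}{\eqn{V = base + A\cos(2\pi f t - \phi(x,y))}
#'     with a linear spatial phase gradient: pure phase waves, no diffusive
#'     content.}
#'   \item{noise_movie}{i.i.d. Gaussian noise (seeded, reproducible).}
#' }
#'
#' @param kind Movie kind (see above).
#' @param nx,ny,dx Grid geometry (nodes, mm).
#' @param duration,frame_interval Time grid [ms].
#' @param freq Temporal frequency [Hz] (oscillation or wave passage rate).
#' @param mediator `"Na"` (full-amplitude upstrokes from a -86 mV floor,
#'   Na availability 0.5) or `"Ca"` (small-amplitude waves from a -50 mV
#'   floor, Na availability 1e-6).
#' @param n_spirals 1 or 2 spiral cores (spiral_movie).
#' @param wavelength Spatial wavelength in node units.
#' @param amp,base Amplitude/baseline of the phase-oscillation movie [mV].
#' @param theta Direction of the phase gradient [rad] (phase_osc_movie).
#' @param noise_sd Noise standard deviation [mV].
#' @param seed Integer seed (noise_movie; recorded in the truth record).
#' @return A `frame_series` with `attr(, "truth")` describing the ground
#'   truth (kind, mediator, expected label and frequency).
#' @export
make_movie <- function(kind = c("plane_movie", "spiral_movie", "target_movie",
                                "phase_osc_movie", "noise_movie"),
                       nx = 48, ny = 48, dx = 0.25, duration = 4000,
                       frame_interval = 4, freq = 4, mediator = c("Na", "Ca"),
                       n_spirals = 1, wavelength = 24, amp = 15, base = -40,
                       theta = 0, noise_sd = 1, seed = 1) {
  kind <- match.arg(kind)
  mediator <- match.arg(mediator)
  times <- seq(0, duration, by = frame_interval)
  nf <- length(times)
  X <- matrix(seq_len(nx) - 1, nx, ny)
  Y <- matrix(seq_len(ny) - 1, nx, ny, byrow = TRUE)
  floor_v <- if (mediator == "Na") -86 else -50
  na_avail <- if (mediator == "Na") 0.5 else 1e-6
  peak_v <- if (mediator == "Na") 20 else 0

  # pulse profile on cyclic phase u in [0,1): sharp upstroke, 30% duty
  pulse <- function(u) {
    u <- u %% 1
    out <- rep(0, length(u))
    rise <- u < 0.02
    out[rise] <- u[rise] / 0.02
    high <- u >= 0.02 & u < 0.3
    out[high] <- 1
    fall <- u >= 0.3 & u < 0.4
    out[fall] <- 1 - (u[fall] - 0.3) / 0.1
    out
  }
  # single wave passage: floor before arrival, pulse, then full
  # repolarization to -86 (so the movie is not "sustained")
  wave_once <- function(u, floor_v, peak_v) {
    v <- rep(-86, length(u))
    v[u < 0] <- floor_v
    r <- u >= 0 & u < 0.02
    v[r] <- floor_v + (peak_v - floor_v) * u[r] / 0.02
    h <- u >= 0.02 & u < 0.3
    v[h] <- peak_v
    f <- u >= 0.3 & u < 0.4
    v[f] <- peak_v + (-86 - peak_v) * (u[f] - 0.3) / 0.1
    v
  }

  spatial_phase <- switch(kind,
    plane_movie = X / wavelength,
    target_movie = sqrt((X - (nx - 1) / 2)^2 + (Y - (ny - 1) / 2)^2) / wavelength,
    spiral_movie = {
      if (n_spirals == 1) {
        atan2(Y - (ny - 1) / 2, X - (nx - 1) / 2) / (2 * pi) +
          sqrt((X - (nx - 1) / 2)^2 + (Y - (ny - 1) / 2)^2) / wavelength
      } else {
        a1 <- atan2(Y - (ny - 1) / 2, X - (nx - 1) * 0.25)
        a2 <- atan2(Y - (ny - 1) / 2, X - (nx - 1) * 0.75)
        (a1 - a2) / (2 * pi) +
          sqrt((X - (nx - 1) / 2)^2 + (Y - (ny - 1) / 2)^2) / (2 * wavelength)
      }
    },
    phase_osc_movie = (cos(theta) * X + sin(theta) * Y) / wavelength,
    noise_movie = X * 0)

  V <- array(0, c(nx, ny, nf))
  na <- array(0, c(nx, ny, nf))
  ca <- array(0.5, c(nx, ny, nf))
  if (kind == "phase_osc_movie") {
    for (kf in seq_len(nf))
      V[, , kf] <- base + amp * cos(2 * pi * freq * times[kf] / 1000 -
                                    2 * pi * spatial_phase)
    na[] <- 1e-6
    label <- "OSC"
  } else if (kind == "noise_movie") {
    V[] <- with_seed(seed, stats::rnorm(nx * ny * nf, mean = -85, sd = noise_sd))
    label <- "NOISE"
  } else if (kind %in% c("plane_movie", "target_movie")) {
    for (kf in seq_len(nf)) {
      u <- freq * times[kf] / 1000 - spatial_phase
      V[, , kf] <- wave_once(u, floor_v, peak_v)
    }
    na[] <- na_avail
    label <- "PLAIN_PROPAGATION"
  } else {
    for (kf in seq_len(nf)) {
      u <- freq * times[kf] / 1000 - spatial_phase
      V[, , kf] <- floor_v + (peak_v - floor_v) * pulse(u)
    }
    na[] <- na_avail
    label <- if (n_spirals == 1) "SINGLE_SPIRAL"
             else if (mediator == "Na") "SF_b" else "SF_a"
  }
  new_frame_series(times = times, V = V, na_gate = na, ca_gate = ca, dx = dx,
                   stim_log = tibble::tibble(stim = integer(0),
                                             onset = numeric(0),
                                             amp = numeric(0),
                                             dur = numeric(0)),
                   truth = list(kind = kind, label = label, freq = freq,
                                mediator = if (kind %in% c("plane_movie",
                                                           "spiral_movie",
                                                           "target_movie"))
                                  mediator else NA_character_,
                                seed = seed))
}

#' Decoupled-oscillator tissue state with a spatial phase gradient
#'
#' Builds a `tissue_state` whose nodes are single-cell oscillatory-regime
#' states sampled at different phases of the limit cycle, the phase varying
#' linearly along a chosen direction.  Run with `D = 0` this is the textbook
#' phase-wave medium: the pattern looks like a travelling wave but involves
#' no coupling, so a non-conducting barrier cannot block it.
#'
#' @param nx,ny Grid size.
#' @param params Oscillatory-regime parameters (default
#'   `regime_params("osc")`).
#' @param n_phases Number of distinct limit-cycle samples.
#' @param theta Direction of the phase gradient [rad].
#' @param wavelength Spatial period of the phase ramp in nodes.
#' @param settle_ms Settling time before the limit cycle is sampled [ms].
#' @return A `tissue_state` (all edges conducting; pair with `D = 0`).
#' @export
make_oscillator_state <- function(nx, ny, params = regime_params("osc"),
                                  n_phases = 16, theta = 0, wavelength = 24,
                                  settle_ms = 3000) {
  stopifnot(inherits(params, "tp06_params"))
  # one long settling run, then sample the cycle with short continuations
  base <- cpp_run_cell(as.numeric(cell_state_rest()), params, 0.02, settle_ms,
                       10, 2, 20, settle_ms, FALSE, FALSE)$final_state
  # estimate the oscillation period from a continuation
  probe <- cpp_run_cell(base, params, 0.02, 2000, numeric(0), 2, 0, 1,
                        FALSE, FALSE)
  sp <- trace_power_spectrum(tibble::tibble(t = probe$t, V = probe$V))
  f <- dominant_frequency(sp)
  period <- if (is.finite(f) && f > 0) 1000 / f else 200
  states <- vector("list", n_phases)
  for (k in seq_len(n_phases)) {
    dt_off <- (k - 1) / n_phases * period
    states[[k]] <- if (dt_off == 0) base else
      cpp_run_cell(base, params, 0.02, dt_off, numeric(0), 2, 0, dt_off,
                   FALSE, FALSE)$final_state
  }
  ts <- tissue_state_rest(nx, ny)
  X <- matrix(seq_len(nx) - 1, nx, ny)
  Y <- matrix(seq_len(ny) - 1, nx, ny, byrow = TRUE)
  ph <- ((cos(theta) * X + sin(theta) * Y) / wavelength) %% 1
  idx <- pmin(n_phases, 1L + floor(ph * n_phases))
  for (k in seq_len(n_phases)) {
    nodes <- which(as.vector(idx) == k)
    if (length(nodes))
      ts$state[nodes, ] <- matrix(states[[k]], nrow = length(nodes),
                                  ncol = 19, byrow = TRUE)
  }
  ts
}
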