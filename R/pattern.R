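#' Phase-singularity counts from the Hilbert phase of V
#'
#' Computes each node's instantaneous phase (analytic signal of the
#' mean-removed voltage over the analysis window) and counts phase
#' singularities per evaluated frame by the topological charge of every
#' grid plaquette (winding number \eqn{\pm 2\pi}).  A single stable spiral
#' has one persistent singularity; breakup produces many.
#'
#' @param fs A `frame_series`.
#' @param t_min,t_max Analysis window [ms]; defaults to the full record.
#' @param n_eval Number of frames (evenly spread over the window) on which
#'   singularities are counted.
#' @return Tibble with `t` and `count`.
#' @export
phase_singularities <- function(fs, t_min = NULL, t_max = NULL, n_eval = 9) {
  stopifnot(inherits(fs, "frame_series"))
  if (is.null(t_min)) t_min <- min(fs$times)
  if (is.null(t_max)) t_max <- max(fs$times)
  keep <- which(fs$times >= t_min & fs$times <= t_max)
  if (length(keep) < 8) stop("analysis window too short", call. = FALSE)
  d <- dim(fs$V); nx <- d[1]; ny <- d[2]; nt <- length(keep)
  m <- matrix(fs$V[, , keep], nrow = nx * ny, ncol = nt)
  m <- m - rowMeans(m)
  # analytic signal along time
  ft <- stats::mvfft(t(m))
  h <- numeric(nt)
  if (nt %% 2 == 0) {
    h[c(1, nt / 2 + 1)] <- 1
    h[2:(nt / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((nt + 1) / 2)] <- 2
  }
  analytic <- stats::mvfft(ft * h, inverse = TRUE) / nt
  phase <- Arg(t(analytic))                     # (nx*ny) x nt
  eval_idx <- unique(round(seq(1, nt, length.out = n_eval)))
  wrap <- function(a) (a + pi) %% (2 * pi) - pi
  counts <- vapply(eval_idx, function(k) {
    P <- matrix(phase[, k], nx, ny)
    a <- P[-nx, -ny]; b <- P[-1, -ny]; c2 <- P[-1, -1]; d2 <- P[-nx, -1]
    w <- wrap(b - a) + wrap(c2 - b) + wrap(d2 - c2) + wrap(a - d2)
    sum(abs(w) > pi)
  }, numeric(1))
  tibble::tibble(t = fs$times[keep][eval_idx], count = counts)
}

# TRUE if any sampled node shows an EAD-type plateau reversal:
# a local minimum above `plateau_floor` followed by a rise >= rise_min,
# occurring >= blank ms after that node's preceding upstroke.
tissue_ead_occurred <- function(fs, cfg = pattern_config(),
                                class_cfg = classifier_config()) {
  d <- dim(fs$V); sn <- sample_nodes(d[1], d[2], cfg$stride)
  for (y in sn$ys) for (x in sn$xs) {
    v <- fs$V[x, y, ]; t <- fs$times
    up <- upstrokes_1d(t, v, cfg$v_thresh)
    if (!nrow(up)) next
    mins <- local_minima(v)
    mins <- mins[v[mins] > class_cfg$plateau_floor]
    for (i in mins) {
      prev_up <- up$t[up$t <= t[i]]
      if (!length(prev_up)) next
      if (t[i] - max(prev_up) < class_cfg$blank_after_upstroke) next
      if (max(v[i:length(v)]) - v[i] >= class_cfg$rise_min) return(TRUE)
    }
  }
  FALSE
}

#' Classify the emergent pattern of a 2D run
#'
#' Applies the decision rules distinguishing the pattern classes:
#' \itemize{
#'   \item not sustained: `SELF_TERMINATED_SFa` if wavebreaks (>= 2 phase
#'     singularities) occurred before the activity died, else
#'     `NO_SUSTAINED_EAD` if EAD reversals occurred anywhere, else
#'     `PLAIN_PROPAGATION`;
#'   \item sustained: `OSC` when no upstroke is Na-mediated, every sampled
#'     node's V amplitude stays below `osc_amp_max`, and (when available)
#'     the barrier test reports phase waves; `SINGLE_SPIRAL` when exactly
#'     one phase singularity persists and no breakup occurred; otherwise
#'     `SF_a` when the Na-mediated fraction is below `sf_split`, else
#'     `SF_b`.
#' }
#' The Na fraction is always reported alongside the discrete label: the
#' SF_a/SF_b transition is gradual, with no sharp boundary.
#'
#' @param fs A `frame_series` with gate products.
#' @param cfg Thresholds from [pattern_config()].
#' @param class_cfg Single-cell classifier thresholds (EAD detection).
#' @param phase_verdict Optional result of [phase_wave_test()]
#'   (`"PHASE_WAVES"`/`"TRIGGER_WAVES"`) to fold into the OSC rule.
#' @param t_developed Start of the developed-state scoring window [ms];
#'   default: the second half of the record.
#' @param t_after_last_stim Optional override of the sustainment deadline
#'   (see [sustained_activity()]).
#' @return A `pattern_report`; see [tidy.pattern_report()].
#' @export
classify_pattern <- function(fs, cfg = pattern_config(),
                             class_cfg = classifier_config(),
                             phase_verdict = NULL, t_developed = NULL,
                             t_after_last_stim = NULL) {
  stopifnot(inherits(fs, "frame_series"))
  if (is.null(t_developed)) t_developed <- mean(range(fs$times))
  sustained <- sustained_activity(fs, t_after_last_stim, cfg)
  att <- attribute_waves(fs, cfg, t_min = t_developed)
  na_f <- attr(att, "na_fraction")
  sp <- mean_power_spectrum(fs, t_min = t_developed, require_resolution = NULL)
  ps_all <- phase_singularities(fs, n_eval = 12)
  ps_dev <- ps_all[ps_all$t >= t_developed, ]
  # ignore the formation transient right after a stimulus (an S2 wavefront
  # briefly reads as an extra phase defect)
  last_stim <- if (!is.null(fs$stim_log) && nrow(fs$stim_log))
    max(fs$stim_log$onset, 0, na.rm = TRUE) else 0
  ps_settled <- ps_all[ps_all$t > last_stim + 300, ]
  breakup <- any(ps_settled$count >= 2)
  persistent <- if (nrow(ps_dev)) median(ps_dev$count) else 0
  d <- dim(fs$V); sn <- sample_nodes(d[1], d[2], cfg$stride)
  dev <- fs$times >= t_developed
  sub <- fs$V[sn$xs, sn$ys, dev, drop = FALSE]
  amp <- apply(sub, c(1, 2), function(v) max(v) - min(v))
  minv <- apply(sub, c(1, 2), min)
  ead_occurred <- tissue_ead_occurred(fs, cfg, class_cfg)

  label <- if (!sustained) {
    if (breakup) "SELF_TERMINATED_SFa"
    else if (ead_occurred) "NO_SUSTAINED_EAD"
    else "PLAIN_PROPAGATION"
  } else {
    osc_like <- (is.na(na_f) || na_f == 0) && max(amp) < cfg$osc_amp_max &&
      (is.null(phase_verdict) || phase_verdict == "PHASE_WAVES")
    if (osc_like) "OSC"
    else if (persistent == 1 && !breakup) "SINGLE_SPIRAL"
    else if (is.na(na_f)) "UNCLASSIFIED"
    else if (na_f < cfg$sf_split) "SF_a"
    else "SF_b"
  }
  structure(list(label = label, sustained = sustained,
                 na_fraction = na_f,
                 dominant_frequencies = spectral_peaks(sp)$freq,
                 min_v = c(min = min(minv), median = median(minv)),
                 evidence = list(attribution = att, spectrum = sp,
                                 singularities = ps_all,
                                 amplitude_max = max(amp),
                                 ead_occurred = ead_occurred,
                                 breakup = breakup,
                                 phase_verdict = phase_verdict,
                                 cfg = cfg)),
            class = "pattern_report")
}

#' @export
print.pattern_report <- function(x, ...) {
  cat(sprintf("pattern: %s (%ssustained)\n", x$label,
              if (x$sustained) "" else "not "))
  cat(sprintf("  na_fraction = %s, dominant f = %s Hz, min V = %.1f mV\n",
              format(x$na_fraction, digits = 3),
              if (length(x$dominant_frequencies))
                format(x$dominant_frequencies[1], digits = 3) else "none",
              x$min_v["min"]))
  invisible(x)
}

#' Tidy a pattern report
#'
#' @param x A `pattern_report`.
#' @param ... Unused.
#' @return One-row tibble: label, sustainment, Na fraction, dominant
#'   frequency, amplitude and minimum-voltage summaries.
#' @export
tidy.pattern_report <- function(x, ...) {
  tibble::tibble(label = x$label, sustained = x$sustained,
                 na_fraction = x$na_fraction,
                 dominant_freq = if (length(x$dominant_frequencies))
                   x$dominant_frequencies[1] else NA_real_,
                 amplitude_max = x$evidence$amplitude_max,
                 min_v = x$min_v[["min"]],
                 ead_occurred = x$evidence$ead_occurred,
                 breakup = x$evidence$breakup)
}

#' Barrier-grid test: trigger waves or phase waves?
#'
#' Continues a developed pattern after imposing a non-conducting square
#' barrier lattice.  Diffusion-mediated (trigger) waves are absorbed at the
#' barriers: activity dies or stays confined to single compartments.  Phase
#' waves -- apparent propagation from a spatial gradient of oscillation
#' phase -- need no coupling and keep "crossing" the barriers unharmed.
#' The verdict is `PHASE_WAVES` when at least `phase_frac` of the
#' compartments remain active in the last quarter of the test window,
#' `TRIGGER_WAVES` otherwise.
#'
#' @param cfg A `tissue_config` matching the state's grid.
#' @param developed_state A `tissue_state` holding the developed pattern.
#' @param block,thickness Barrier lattice pitch / thickness in nodes.
#' @param test_window Continuation length [ms].
#' @param pat_cfg Thresholds from [pattern_config()].
#' @param phase_frac Active-compartment fraction above which the pattern
#'   counts as phase waves.
#' @return `"PHASE_WAVES"` or `"TRIGGER_WAVES"`, with the active-compartment
#'   fraction and the continued run attached as attributes.
#' @export
phase_wave_test <- function(cfg, developed_state, block = 40, thickness = 1,
                            test_window = 2000, pat_cfg = pattern_config(),
                            phase_frac = 0.5) {
  stopifnot(inherits(cfg, "tissue_config"),
            inherits(developed_state, "tissue_state"))
  if (!any(developed_state$state[, 1] > pat_cfg$v_active))
    stop("no sustained activity in the input state; barrier test needs a developed pattern",
         call. = FALSE)
  st <- apply_barrier_grid(developed_state, block, thickness)
  cfg2 <- cfg
  cfg2$protocol <- "none"
  cfg2$duration <- test_window
  cfg2$barrier <- NULL
  fs <- run_tissue(cfg2, init = st)
  tail_w <- fs$times >= max(fs$times) - test_window / 4
  nxc <- ceiling(cfg$nx / block); nyc <- ceiling(cfg$ny / block)
  active <- matrix(FALSE, nxc, nyc)
  Vt <- fs$V[, , tail_w, drop = FALSE]
  act_node <- apply(Vt, c(1, 2), max) > pat_cfg$v_active
  for (cx in seq_len(nxc)) for (cy in seq_len(nyc)) {
    xs <- ((cx - 1) * block + 1):min(cx * block, cfg$nx)
    ys <- ((cy - 1) * block + 1):min(cy * block, cfg$ny)
    active[cx, cy] <- any(act_node[xs, ys])
  }
  frac <- mean(active)
  verdict <- if (frac >= phase_frac) "PHASE_WAVES" else "TRIGGER_WAVES"
  structure(verdict, active_fraction = frac, continued = fs)
}
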