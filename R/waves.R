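#' Thresholds for wave attribution and pattern classification
#'
#' Config-exposed defaults for the discrimination rules; the underlying
#' transitions are gradual, so every cut is tunable.
#'
#' @param v_thresh Upstroke detection threshold [mV].
#' @param na_floor A wavefront can only be Na-mediated if the pre-upstroke
#'   voltage floor was below this level [mV] (above it I_Na is inactivated).
#' @param na_avail_min Minimum Na availability \eqn{m^3 h j} at the crossing
#'   for a Na-mediated upstroke.
#' @param sf_split SF_a/SF_b boundary on the Na-mediated wave fraction.
#' @param osc_amp_max Oscillatory patterns keep per-node V amplitude below
#'   this [mV].
#' @param v_active Node counts as active above this voltage [mV].
#' @param cv_est Conduction-velocity estimate used for the domain-crossing
#'   time in the sustainment deadline [mm/ms].
#' @param stride Node subsampling stride for per-node time-series analyses.
#' @return A list of thresholds.
#' @export
pattern_config <- function(v_thresh = -30, na_floor = -60, na_avail_min = 0.01,
                           sf_split = 0.2, osc_amp_max = 40, v_active = -70,
                           cv_est = 0.5, stride = 4) {
  list(v_thresh = v_thresh, na_floor = na_floor, na_avail_min = na_avail_min,
       sf_split = sf_split, osc_amp_max = osc_amp_max, v_active = v_active,
       cv_est = cv_est, stride = stride)
}

sample_nodes <- function(nx, ny, stride) {
  xs <- seq(1, nx, by = stride)
  ys <- seq(1, ny, by = stride)
  list(xs = xs, ys = ys,
       idx = as.integer(outer(xs, (ys - 1) * nx, `+`)))
}

# upstroke times and pre-upstroke floors for one voltage series.
# Returns tibble(frame, t, floor): upward crossings of v_thresh, each with
# the minimum V since the previous downward crossing (or series start).
upstrokes_1d <- function(t, v, v_thresh) {
  above <- v > v_thresh
  n <- length(v)
  cross_up <- which(above[-1] & !above[-n]) + 1L
  if (!length(cross_up))
    return(tibble::tibble(frame = integer(0), t = numeric(0),
                          floor = numeric(0)))
  cross_dn <- which(!above[-1] & above[-n]) + 1L
  floors <- vapply(cross_up, function(i) {
    prev_dn <- cross_dn[cross_dn < i]
    lo <- if (length(prev_dn)) max(prev_dn) else 1L
    min(v[lo:i])
  }, numeric(1))
  tibble::tibble(frame = cross_up, t = t[cross_up], floor = floors)
}

#' Attribute wavefront upstrokes to sodium or L-type calcium current
#'
#' Scans sampled nodes for upward crossings of `v_thresh` and labels each
#' upstroke Na-mediated if the pre-upstroke voltage floor was below
#' `na_floor` (so I_Na had recovered from inactivation) and the Na
#' availability \eqn{m^3 h j} at the crossing exceeds `na_avail_min`;
#' otherwise Ca-mediated.  Spiral fibrillation type a and the oscillatory
#' regime are maintained almost purely by Ca-mediated waves; type b retains
#' a substantial Na-mediated fraction.
#'
#' @param fs A `frame_series` recorded with gate products.
#' @param cfg Thresholds from [pattern_config()].
#' @param t_min Ignore upstrokes before this time [ms] (e.g. to skip the
#'   initiation transient and score only the developed state).
#' @return A `wave_attribution`: tibble of per-upstroke records (`x`, `y`,
#'   `t`, `floor`, `na_avail`, `ca_gate`, `mediator`), with aggregate
#'   `na_fraction` / `ca_fraction` as attributes (use [glance()]).
#' @export
attribute_waves <- function(fs, cfg = pattern_config(), t_min = 0) {
  stopifnot(inherits(fs, "frame_series"))
  if (is.null(fs$na_gate))
    stop("frame series lacks gate products; run with record_gates = TRUE",
         call. = FALSE)
  d <- dim(fs$V); nx <- d[1]; ny <- d[2]
  sn <- sample_nodes(nx, ny, cfg$stride)
  rows <- list()
  for (y in sn$ys) for (x in sn$xs) {
    up <- upstrokes_1d(fs$times, fs$V[x, y, ], cfg$v_thresh)
    up <- up[up$t >= t_min, ]
    if (!nrow(up)) next
    up$na_avail <- fs$na_gate[x, y, up$frame]
    up$ca_gate <- fs$ca_gate[x, y, up$frame]
    up$x <- x; up$y <- y
    rows[[length(rows) + 1L]] <- up
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(frame = integer(0), t = numeric(0), floor = numeric(0),
                   na_avail = numeric(0), ca_gate = numeric(0),
                   x = integer(0), y = integer(0))
  out$mediator <- ifelse(out$floor < cfg$na_floor &
                         out$na_avail > cfg$na_avail_min, "Na", "Ca")
  naf <- if (nrow(out)) mean(out$mediator == "Na") else NA_real_
  structure(out, class = unique(c("wave_attribution", class(out))),
            na_fraction = naf,
            ca_fraction = if (is.na(naf)) NA_real_ else 1 - naf,
            cfg = cfg)
}

#' @export
glance.wave_attribution <- function(x, ...) {
  tibble::tibble(n_upstrokes = nrow(x),
                 na_fraction = attr(x, "na_fraction"),
                 ca_fraction = attr(x, "ca_fraction"))
}

#' Interbeat intervals and per-beat amplitudes at sampled nodes
#'
#' Intervals between successive upstrokes at each sampled node; each beat's
#' amplitude is the V excursion (max - min) between the bounding upstrokes.
#' The interval/amplitude joint distribution separates the wave populations
#' of mixed-amplitude fibrillation.
#'
#' @param fs A `frame_series`.
#' @param cfg Thresholds from [pattern_config()].
#' @param t_min Ignore activity before this time [ms].
#' @param amplitude_bands Band edges [mV] for the joint histogram.
#' @return List with `beats` (tibble: `x`, `y`, `t`, `interval`,
#'   `amplitude`) and `histogram` (tibble: interval bin midpoint, amplitude
#'   band, count).
#' @export
interbeat_intervals <- function(fs, cfg = pattern_config(), t_min = 0,
                                amplitude_bands = c(0, 40, 80, 140)) {
  stopifnot(inherits(fs, "frame_series"))
  d <- dim(fs$V); nx <- d[1]; ny <- d[2]
  sn <- sample_nodes(nx, ny, cfg$stride)
  rows <- list()
  for (y in sn$ys) for (x in sn$xs) {
    v <- fs$V[x, y, ]
    up <- upstrokes_1d(fs$times, v, cfg$v_thresh)
    up <- up[up$t >= t_min, ]
    if (nrow(up) < 2) next
    f <- up$frame
    amp <- vapply(seq_len(nrow(up) - 1), function(k) {
      seg <- v[f[k]:f[k + 1]]
      max(seg) - min(seg)
    }, numeric(1))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      x = x, y = y, t = up$t[-1],
      interval = diff(up$t), amplitude = amp)
  }
  beats <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(x = integer(0), y = integer(0), t = numeric(0),
                   interval = numeric(0), amplitude = numeric(0))
  hist <- if (nrow(beats)) {
    beats |>
      dplyr::mutate(
        amp_band = cut(amplitude, amplitude_bands, include.lowest = TRUE),
        ibi_bin = round(interval / 25) * 25) |>
      dplyr::count(ibi_bin, amp_band)
  } else tibble::tibble(ibi_bin = numeric(0), amp_band = factor(),
                        n = integer(0))
  list(beats = beats, histogram = hist)
}

#' Is electrical activity sustained after the initiation transient?
#'
#' TRUE iff any node is above `v_active` beyond the sustainment deadline:
#' by default 3 s after the last stimulus plus one domain-crossing time (a
#' single wave launched by the last stimulus must have cleared the domain by
#' then).
#'
#' @param fs A `frame_series`.
#' @param t_after_last_stim Override the deadline offset [ms]; default
#'   `3000 +` domain crossing time at `cfg$cv_est`.
#' @param cfg Thresholds from [pattern_config()].
#' @return Logical.
#' @export
sustained_activity <- function(fs, t_after_last_stim = NULL,
                               cfg = pattern_config()) {
  stopifnot(inherits(fs, "frame_series"))
  last_stim <- if (!is.null(fs$stim_log) && nrow(fs$stim_log))
    max(fs$stim_log$onset, 0, na.rm = TRUE) else 0
  if (is.null(t_after_last_stim))
    t_after_last_stim <- 3000 + dim(fs$V)[1] * fs$dx / cfg$cv_est
  deadline <- last_stim + t_after_last_stim
  keep <- fs$times > deadline
  if (!any(keep))
    stop(sprintf("run ends at %g ms, before the sustainment deadline %g ms",
                 max(fs$times), deadline), call. = FALSE)
  any(fs$V[, , keep] > cfg$v_active)
}

#' Space-time voltage matrix along a grid line
#'
#' V along one row or column for every frame; the standard view for
#' watching EAD wavebreaks detach from a waveback.
#'
#' @param fs A `frame_series`.
#' @param row,column 1-based index of the line (give exactly one).
#' @return A `line_profile`: matrix (space along the line x frames) with
#'   times/positions as attributes.
#' @export
line_profile <- function(fs, row = NULL, column = NULL) {
  stopifnot(inherits(fs, "frame_series"))
  d <- dim(fs$V)
  if (is.null(row) == is.null(column))
    stop("give exactly one of row or column", call. = FALSE)
  if (!is.null(row)) {
    if (row < 1 || row > d[2]) stop("row index out of range", call. = FALSE)
    m <- fs$V[, row, ]
  } else {
    if (column < 1 || column > d[1]) stop("column index out of range", call. = FALSE)
    m <- fs$V[column, , ]
  }
  structure(m, class = c("line_profile", "matrix"),
            times = fs$times, dx = fs$dx)
}

#' Plot a space-time line profile
#'
#' @param object A `line_profile`.
#' @param ... Unused.
#' @return A ggplot raster of V(space, time).
#' @export
autoplot.line_profile <- function(object, ...) {
  df <- tidyr::expand_grid(s = seq_len(nrow(object)),
                           k = seq_len(ncol(object)))
  df$V <- as.vector(object)
  df$t <- attr(object, "times")[df$k]
  df$pos <- (df$s - 1) * attr(object, "dx")
  ggplot2::ggplot(df, ggplot2::aes(t, pos, fill = V)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "time [ms]", y = "position [mm]", fill = "V [mV]") +
    ggplot2::theme_minimal()
}
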