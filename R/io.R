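#' Write / read a frame series as plain-text artifacts
#'
#' Frames are stored as one CSV matrix per channel per frame plus a JSON
#' metadata file (`meta.json`: grid, times, channels, model multipliers), so
#' a run is inspectable with any text tooling and round-trips exactly.
#'
#' @param fs A `frame_series`.
#' @param dir Output directory (created if needed).
#' @param channels Channels to write (subset of `"V"`, `"na_gate"`,
#'   `"ca_gate"`).
#' @return `write_frames` returns `dir` invisibly; `read_frames` the
#'   reconstructed `frame_series`.
#' @export
write_frames <- function(fs, dir, channels = c("V", "na_gate", "ca_gate")) {
  stopifnot(inherits(fs, "frame_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- intersect(channels, c("V", "na_gate", "ca_gate"))
  channels <- channels[!vapply(fs[channels], is.null, logical(1))]
  d <- dim(fs$V)
  meta <- list(nx = d[1], ny = d[2], n_frames = d[3], dx = fs$dx,
               times = fs$times, channels = channels)
  if (!is.null(fs$cfg))
    meta$multipliers <- fs$cfg$params[c("mult_CaL", "mult_Ks", "mult_Kr",
                                        "mult_NaCa", "tau_f_scale")]
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (ch in channels) {
    arr <- fs[[ch]]
    for (k in seq_len(d[3])) {
      f <- file.path(dir, sprintf("%s_%05d.csv", ch, k))
      utils::write.table(arr[, , k], f, sep = ",", row.names = FALSE,
                         col.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  load_ch <- function(ch) {
    arr <- array(NA_real_, c(meta$nx, meta$ny, meta$n_frames))
    for (k in seq_len(meta$n_frames)) {
      f <- file.path(dir, sprintf("%s_%05d.csv", ch, k))
      arr[, , k] <- as.matrix(utils::read.csv(f, header = FALSE))
    }
    arr
  }
  chans <- meta$channels
  new_frame_series(times = meta$times, V = load_ch("V"),
                   na_gate = if ("na_gate" %in% chans) load_ch("na_gate"),
                   ca_gate = if ("ca_gate" %in% chans) load_ch("ca_gate"),
                   dx = meta$dx)
}

#' Export an AP trace (t, V and any recorded currents) as CSV
#'
#' @param tr An `ap_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(tr, path) {
  utils::write.csv(tibble::as_tibble(tr), path, row.names = FALSE)
  invisible(path)
}

#' Plot one frame of a voltage movie
#'
#' @param object A `frame_series`.
#' @param t Time of the frame to show [ms] (nearest frame is used).
#' @param channel `"V"`, `"na_gate"` or `"ca_gate"`.
#' @param ... Unused.
#' @return A ggplot raster of the frame.
#' @export
autoplot.frame_series <- function(object, t = max(object$times),
                                  channel = "V", ...) {
  k <- which.min(abs(object$times - t))
  m <- object[[channel]][, , k]
  df <- tidyr::expand_grid(y = seq_len(ncol(m)), x = seq_len(nrow(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x, y, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s at t = %g ms", channel,
                                  object$times[k]),
                  fill = channel) +
    ggplot2::theme_minimal()
}

#' Plane-wave conduction velocity by front tracking
#'
#' Tracks the first upward crossing of `v_thresh` along one row and fits
#' arrival time against position between two x-positions.
#'
#' @param fs A `frame_series` containing a propagating wave.
#' @param row Row (y index) along which to track; default mid-domain.
#' @param x_range Fractional x-window used for the fit (avoids stimulus and
#'   boundary artifacts).
#' @param v_thresh Front detection threshold [mV].
#' @return Conduction velocity [mm/ms].
#' @export
conduction_velocity <- function(fs, row = NULL, x_range = c(0.25, 0.75),
                                v_thresh = -30) {
  stopifnot(inherits(fs, "frame_series"))
  d <- dim(fs$V)
  if (is.null(row)) row <- round(d[2] / 2)
  xs <- seq(max(1, round(x_range[1] * d[1])), round(x_range[2] * d[1]))
  arrival <- vapply(xs, function(x) {
    v <- fs$V[x, row, ]
    i <- which(v > v_thresh)[1]
    if (is.na(i)) NA_real_ else fs$times[i]
  }, numeric(1))
  ok <- is.finite(arrival)
  if (sum(ok) < 2) stop("front did not cross the tracking window", call. = FALSE)
  fit <- stats::lm(arrival[ok] ~ xs[ok])
  1 / unname(stats::coef(fit)[2]) * fs$dx
}
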