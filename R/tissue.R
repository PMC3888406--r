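#' Configuration for a 2D monodomain tissue run
#'
#' Assembles and validates everything a tissue simulation needs: grid,
#' numerics, ionic-model multipliers, initiation protocol and optional
#' barrier grid.  Defaults are the standard TP06 2D settings: `dx` 0.25 mm,
#' `dt` 0.02 ms, `D` 0.00154 cm\eqn{^2}/ms.
#'
#' @param nx,ny Grid size in nodes (>= 10).
#' @param dx Node spacing in mm.
#' @param dt Integration step in ms; must satisfy the explicit-scheme
#'   stability bound \eqn{dt \le dx^2 / (4D)}.
#' @param D Diffusion coefficient in cm\eqn{^2}/ms.
#' @param duration Simulated time in ms.
#' @param frame_interval Frame output interval in ms (multiple of `dt`).
#' @param protocol One of `"p1"` (single plane-wave stimulus from a strip on
#'   the left edge), `"p2"` (S1--S2 cross-field: the S2 quarter-domain
#'   stimulus fires automatically when the S1 waveback sweeps past the
#'   middle of the S2 region; see [protocol_schedule()]),
#'   `"paced"` (periodic P1 restimulation), `"none"`.
#' @param params A `tp06_params` object (see [make_params()]).
#' @param stim_amp,stim_dur Stimulus amplitude (pA/pF) and duration (ms).
#' @param strip_width Width in nodes of the P1 strip at the left edge.
#' @param strip_height Height in nodes of the strip (default: full edge).
#' @param pacing_period,pacing_epoch For `"paced"`: re-stimulation period in
#'   [300, 1000] ms and total pacing time in ms.
#' @param barrier Optional `list(block =, thickness = 1, at = 0)`: impose a
#'   non-conducting square barrier lattice of pitch `block` nodes at time
#'   `at` ms (edges cut; `thickness` adjacent edge layers).
#' @param record_gates Record Na-availability (\eqn{m^3 h j}) and L-type Ca
#'   gate (\eqn{d f f_2 f_{Cass}}) frames alongside voltage.
#' @param diffusion_only Disable the ionic terms (pure diffusion; testing).
#' @param euler_gates Forward-Euler gate integration (fidelity checks).
#' @return A validated `tissue_config` list.
#' @export
tissue_config <- function(nx = 100, ny = 100, dx = 0.25, dt = 0.02,
                          D = 0.00154, duration = 2000, frame_interval = 2,
                          protocol = c("p1", "p2", "paced", "none"),
                          params = make_params(),
                          stim_amp = 20, stim_dur = 2,
                          strip_width = 6, strip_height = NULL,
                          pacing_period = 1000, pacing_epoch = 3000,
                          barrier = NULL,
                          record_gates = TRUE, diffusion_only = FALSE,
                          euler_gates = FALSE) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(params, "tp06_params"))
  if (nx < 10 || ny < 10) stop("grid must be at least 10 x 10 nodes", call. = FALSE)
  if (!diffusion_only && dt > dx^2 / (4 * D * 100))
    stop(sprintf("dt = %g violates the explicit stability bound dx^2/(4D) = %g ms",
                 dt, dx^2 / (4 * D * 100)), call. = FALSE)
  if (abs(frame_interval / dt - round(frame_interval / dt)) > 1e-9)
    stop("frame_interval must be a multiple of dt", call. = FALSE)
  if (protocol == "paced" && (pacing_period < 300 || pacing_period > 1000))
    stop("pacing_period must lie in [300, 1000] ms", call. = FALSE)
  if (is.null(strip_height)) strip_height <- ny
  if (strip_width > nx || strip_height > ny)
    stop("stimulus strip exceeds the domain", call. = FALSE)
  if (!is.null(barrier)) {
    barrier <- utils::modifyList(list(block = 40, thickness = 1, at = 0), barrier)
    if (barrier$block < 4) stop("barrier block must be >= 4 nodes", call. = FALSE)
    if (barrier$thickness >= barrier$block)
      stop("barrier thickness must be smaller than the block size", call. = FALSE)
  }
  structure(list(nx = nx, ny = ny, dx = dx, dt = dt, D = D,
                 duration = duration, frame_interval = frame_interval,
                 protocol = protocol, params = params,
                 stim_amp = stim_amp, stim_dur = stim_dur,
                 strip_width = strip_width, strip_height = strip_height,
                 pacing_period = pacing_period, pacing_epoch = pacing_epoch,
                 barrier = barrier, record_gates = record_gates,
                 diffusion_only = diffusion_only, euler_gates = euler_gates),
            class = "tissue_config")
}

#' Resting tissue state
#'
#' Every node at the TP06 resting state, all internal edges conducting.
#'
#' @param nx,ny Grid size in nodes.
#' @return A `tissue_state`: list with the per-node state matrix (`nx*ny`
#'   rows, node index `x + nx*(y-1)`), edge coupling masks `conn_r`/`conn_u`
#'   and the simulation clock.
#' @export
tissue_state_rest <- function(nx, ny) {
  N <- nx * ny
  s <- matrix(rep(as.numeric(cell_state_rest()), each = N), nrow = N)
  colnames(s) <- state_field_names()
  new_tissue_state(nx, ny, s, rep(TRUE, N), rep(TRUE, N), 0)
}

new_tissue_state <- function(nx, ny, state, conn_r, conn_u, t) {
  structure(list(nx = nx, ny = ny, state = state,
                 conn_r = conn_r, conn_u = conn_u, t = t),
            class = "tissue_state")
}

node_index <- function(x, y, nx) x + nx * (y - 1)

#' Impose a non-conducting square barrier lattice on a tissue state
#'
#' Cuts the coupling along a square lattice of pitch `block` nodes, splitting
#' the domain into electrically isolated compartments.  Cell states are
#' untouched; only the edge mask changes.  This is the non-conducting-barrier
#' discriminator between trigger waves (absorbed) and phase waves
#' (unaffected).
#'
#' @param ts A `tissue_state`.
#' @param block Lattice pitch in nodes (>= 4).
#' @param thickness Number of adjacent edge layers to cut (< `block`).
#' @return The modified `tissue_state`.
#' @export
apply_barrier_grid <- function(ts, block, thickness = 1) {
  stopifnot(inherits(ts, "tissue_state"))
  if (block < 4) stop("block must be >= 4 nodes", call. = FALSE)
  if (thickness >= block) stop("thickness must be < block", call. = FALSE)
  nx <- ts$nx; ny <- ts$ny
  for (j in seq_len(thickness) - 1L) {
    xcuts <- seq(block, nx - 1, by = block) + j    # edge between x and x+1
    xcuts <- xcuts[xcuts < nx]
    for (xc in xcuts)
      ts$conn_r[node_index(xc, seq_len(ny), nx)] <- FALSE
    ycuts <- seq(block, ny - 1, by = block) + j
    ycuts <- ycuts[ycuts < ny]
    for (yc in ycuts)
      ts$conn_u[node_index(seq_len(nx), yc, nx)] <- FALSE
  }
  ts
}

strip_nodes <- function(cfg) {
  y0 <- floor((cfg$ny - cfg$strip_height) / 2)
  ys <- seq_len(cfg$strip_height) + y0
  as.integer(outer(seq_len(cfg$strip_width), (ys - 1) * cfg$nx, `+`))
}

quarter_nodes <- function(cfg) {
  xs <- seq_len(floor(cfg$nx / 2))
  ys <- seq_len(floor(cfg$ny / 2))
  as.integer(outer(xs, (ys - 1) * cfg$nx, `+`))
}

#' Stimulus schedule for a protocol
#'
#' Expands the protocol named in a [tissue_config()] into explicit stimulus
#' entries (onset, duration, amplitude, node set).  P2's S2 entry carries
#' `onset = NA`: it fires when the S1 waveback sweeps past the middle of
#' the S2 region (the column at nx/4 repolarizes below -40 mV after having
#' been excited), so the premature stimulus lands on the refractory
#' gradient and curls into a spiral.
#'
#' @param cfg A `tissue_config`.
#' @return List of stimulus entries.
#' @export
protocol_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "tissue_config"))
  strip <- strip_nodes(cfg)
  mk <- function(onset, nodes) list(onset = onset, dur = cfg$stim_dur,
                                    amp = cfg$stim_amp, nodes = nodes)
  switch(cfg$protocol,
    none = list(),
    p1 = list(mk(10, strip)),
    p2 = list(mk(10, strip), mk(NA_real_, quarter_nodes(cfg))),
    paced = {
      onsets <- seq(10, 10 + cfg$pacing_epoch, by = cfg$pacing_period)
      onsets <- onsets[onsets + cfg$stim_dur < cfg$duration]
      lapply(onsets, mk, nodes = strip)
    })
}

#' Run a 2D monodomain tissue simulation
#'
#' Integrates the monodomain reaction--diffusion equation
#' \eqn{\partial V/\partial t = D \nabla^2 V - (I_{ion} + I_{stim})} on an
#' isotropic grid with Neumann (no-flux) boundaries and a mask-aware 5-point
#' Laplacian, executing the configured initiation protocol and recording
#' frames of V (and optionally of the Na and Ca gate products) every
#' `frame_interval` ms.  Deterministic: identical configs give bit-identical
#' frame stacks.
#'
#' @param cfg A `tissue_config`.
#' @param init Optional initial `tissue_state` (defaults to rest); lets a
#'   developed pattern be continued, e.g. after [apply_barrier_grid()].
#' @param stims Optional explicit stimulus schedule overriding the protocol.
#' @return A `frame_series`: list with `times` [ms], arrays `V` (and
#'   `na_gate`, `ca_gate`) of dim `nx x ny x n_frames`, the realized stimulus
#'   log, the final `tissue_state`, and grid metadata.
#' @export
run_tissue <- function(cfg, init = NULL, stims = NULL) {
  stopifnot(inherits(cfg, "tissue_config"))
  ts <- if (is.null(init)) tissue_state_rest(cfg$nx, cfg$ny) else init
  if (!is.null(init)) stopifnot(inherits(init, "tissue_state"),
                                init$nx == cfg$nx, init$ny == cfg$ny)
  if (!is.null(cfg$barrier) && cfg$barrier$at <= 0)
    ts <- apply_barrier_grid(ts, cfg$barrier$block, cfg$barrier$thickness)
  if (is.null(stims)) stims <- protocol_schedule(cfg)

  run_leg <- function(ts, duration, stims) {
    res <- cpp_run_tissue(ts$state, cfg$nx, cfg$ny, ts$conn_r, ts$conn_u,
                          cfg$params, cfg$D, cfg$dx, cfg$dt, duration, stims,
                          0.25, -10, -40, cfg$frame_interval, cfg$record_gates,
                          cfg$diffusion_only, cfg$euler_gates)
    res
  }

  t_barrier <- if (!is.null(cfg$barrier) && cfg$barrier$at > 0)
    cfg$barrier$at else Inf
  if (is.finite(t_barrier) && t_barrier < cfg$duration) {
    res1 <- run_leg(ts, t_barrier, stims)
    st <- ts; st$state <- res1$final_state
    st <- apply_barrier_grid(st, cfg$barrier$block, cfg$barrier$thickness)
    # remaining stimuli shifted into the second leg's clock
    stims2 <- lapply(stims, function(s) {
      if (is.na(s$onset) || s$onset >= t_barrier) {
        s$onset <- if (is.na(s$onset)) NA_real_ else s$onset - t_barrier
        s
      } else NULL
    })
    stims2 <- Filter(Negate(is.null), stims2)
    res2 <- run_leg(st, cfg$duration - t_barrier, stims2)
    nf1 <- length(res1$times)
    glue <- function(a, b) {
      arr <- array(0, c(cfg$nx, cfg$ny, nf1 + dim(b)[3] - 1))
      arr[, , seq_len(nf1)] <- a
      arr[, , nf1 + seq_len(dim(b)[3] - 1)] <- b[, , -1, drop = FALSE]
      arr
    }
    out <- list(times = c(res1$times, res2$times[-1] + t_barrier),
                V = glue(res1$V, res2$V),
                stim_onsets = res1$stim_onsets,
                final_state = res2$final_state)
    if (cfg$record_gates) {
      out$na_gate <- glue(res1$na_gate, res2$na_gate)
      out$ca_gate <- glue(res1$ca_gate, res2$ca_gate)
    }
    final_mask <- st
    res <- out
  } else {
    res <- run_leg(ts, cfg$duration, stims)
    final_mask <- ts
  }

  fstate <- new_tissue_state(cfg$nx, cfg$ny, res$final_state,
                             final_mask$conn_r, final_mask$conn_u,
                             ts$t + cfg$duration)
  new_frame_series(times = res$times, V = res$V,
                   na_gate = res$na_gate, ca_gate = res$ca_gate,
                   dx = cfg$dx, cfg = cfg,
                   stim_log = tibble::tibble(
                     stim = seq_along(stims),
                     onset = as.numeric(res$stim_onsets),
                     amp = vapply(stims, `[[`, numeric(1), "amp"),
                     dur = vapply(stims, `[[`, numeric(1), "dur")),
                   final_state = fstate)
}

new_frame_series <- function(times, V, na_gate = NULL, ca_gate = NULL,
                             dx, cfg = NULL, stim_log = NULL,
                             final_state = NULL, truth = NULL) {
  structure(list(times = times, V = V, na_gate = na_gate, ca_gate = ca_gate,
                 dx = dx, cfg = cfg, stim_log = stim_log,
                 final_state = final_state, truth = truth),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  d <- dim(x$V)
  cat(sprintf("frame series: %d x %d nodes, %d frames, t in [%g, %g] ms, dx = %g mm\n",
              d[1], d[2], d[3], min(x$times), max(x$times), x$dx))
  cat(sprintf("  channels: V%s%s\n",
              if (!is.null(x$na_gate)) ", na_gate" else "",
              if (!is.null(x$ca_gate)) ", ca_gate" else ""))
  invisible(x)
}

#' Mask-aware 5-point Laplacian
#'
#' Interior nodes use \eqn{(N+S+E+W-4C)/dx^2}; edges cut by the mask and
#' domain boundaries contribute the centre value, i.e. zero flux, so Neumann
#' boundaries and barriers share one mechanism.
#'
#' @param field Numeric matrix.
#' @param dx Node spacing.
#' @param conn_r,conn_u Logical matrices of the same shape: does the edge
#'   from node (x,y) to (x+1,y) / (x,y+1) conduct?  Default all-conducting.
#' @return Matrix of the same shape.
#' @export
laplacian5 <- function(field, dx, conn_r = NULL, conn_u = NULL) {
  stopifnot(is.matrix(field), all(is.finite(field)))
  if (is.null(conn_r)) conn_r <- matrix(TRUE, nrow(field), ncol(field))
  if (is.null(conn_u)) conn_u <- matrix(TRUE, nrow(field), ncol(field))
  cpp_laplacian5(field, dx, conn_r, conn_u)
}
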