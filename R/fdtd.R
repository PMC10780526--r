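#' Antenna array on the acquisition ring
#'
#' Places `cfg$n_antennas` idealized (Hertzian / line-source) antennas
#' evenly in angle on the circle of radius `cfg$antenna_radius`, starting at
#' `start_angle` (degrees, counter-clockwise from +x). Each antenna is
#' snapped to the nearest solver grid cell; the same cell is used for
#' transmission (soft Ez source) and reception (Ez sample).
#'
#' @param cfg A [domain_config()].
#' @param start_angle Angle of the first antenna, degrees.
#' @return Object of class `antenna_array` with `positions` (n x 2, mm) and
#'   `grid_indices` (n x 2, 1-based interior-grid row/col).
#' @export
antenna_array <- function(cfg, start_angle = 0) {
  validate_domain_config(cfg)
  ang <- (start_angle + (seq_len(cfg$n_antennas) - 1) * 360 / cfg$n_antennas) *
    pi / 180
  pos <- cbind(x = cfg$antenna_radius * cos(ang),
               y = cfg$antenna_radius * sin(ang))
  n <- grid_cells(cfg)
  # interior cell centers: x_i = -L/2 + (i - 0.5) * cell
  idx <- cbind(i = pmin(pmax(round(pos[, 1] / cfg$cell_size +
                                   n / 2 + 0.5), 1), n),
               j = pmin(pmax(round(pos[, 2] / cfg$cell_size +
                                   n / 2 + 0.5), 1), n))
  arr <- list(positions = pos, grid_indices = idx,
              n_antennas = cfg$n_antennas, start_angle = start_angle,
              antenna_radius = cfg$antenna_radius)
  class(arr) <- "antenna_array"
  arr
}

#' @export
print.antenna_array <- function(x, ...) {
  cat(sprintf("%d antennas on a %g mm ring, first at %g deg, %g deg apart\n",
              x$n_antennas, x$antenna_radius, x$start_angle,
              360 / x$n_antennas))
  invisible(x)
}

# Pad interior maps with the matching medium under the CPML and return the
# full-grid maps plus the interior offset.
pad_maps <- function(eps_map, sigma_map, dcfg, scfg) {
  n <- nrow(eps_map)
  npml <- scfg$pml_cells
  N <- n + 2 * npml
  eps <- matrix(dcfg$matching_eps, N, N)
  sig <- matrix(dcfg$matching_sigma, N, N)
  sel <- npml + seq_len(n)
  eps[sel, sel] <- eps_map
  sig[sel, sel] <- sigma_map
  list(eps = eps, sigma = sig, offset = npml, N = N)
}

#' Build a simulation state from a phantom
#'
#' Assembles the full-grid material maps (interior phantom maps padded with
#' the matching medium beneath the absorbing layer), checks the 2D Courant
#' stability bound against the minimum permittivity on the grid, and
#' precomputes the per-cell update coefficients
#' `Ca = (1 - s*dt/2e) / (1 + s*dt/2e)` and
#' `Cb = (dt/(e*dx)) / (1 + s*dt/2e)` (with `e` the absolute permittivity
#' and `s` the conductivity). Field arrays (Ez at cell centers, Hx/Hy on
#' staggered half-cell edges) start at zero.
#'
#' @param phantom A `phantom_case` (or a list with `eps_map`/`sigma_map`
#'   matrices on the solver grid).
#' @param array An [antenna_array()].
#' @param scfg A [solver_config()].
#' @param dcfg The [domain_config()] the phantom was built with.
#' @return Object of class `fdtd_simulation`.
#' @export
build_simulation <- function(phantom, array, scfg, dcfg) {
  n <- grid_cells(dcfg)
  if (!all(dim(phantom$eps_map) == c(n, n)) ||
      !all(dim(phantom$sigma_map) == c(n, n)))
    stop("phantom maps do not match the grid implied by the configuration",
         call. = FALSE)
  if (abs(scfg$dx - dcfg$cell_size * 1e-3) > 1e-12)
    stop("solver dx and domain cell_size disagree", call. = FALSE)
  padded <- pad_maps(phantom$eps_map, phantom$sigma_map, dcfg, scfg)
  eps_min <- min(padded$eps)
  dt_max <- courant_limit(eps_min, scfg$dx)
  if (scfg$dt > dt_max)
    stop(sprintf(paste0("Courant stability violated: dt = %.4g ps exceeds the ",
                        "admissible %.4g ps for eps_min = %.3g"),
                 scfg$dt * 1e12, dt_max * 1e12, eps_min), call. = FALSE)
  eps_abs <- padded$eps * .eps0
  loss <- padded$sigma * scfg$dt / (2 * eps_abs)
  state <- list(eps_r = padded$eps, sigma = padded$sigma,
                Ca = (1 - loss) / (1 + loss),
                Cb = (scfg$dt / (eps_abs * scfg$dx)) / (1 + loss),
                N = padded$N, offset = padded$offset,
                fields = list(Ez = matrix(0, padded$N, padded$N),
                              Hx = matrix(0, padded$N, padded$N - 1),
                              Hy = matrix(0, padded$N - 1, padded$N)),
                scfg = scfg, dcfg = dcfg, array = array,
                eps_min = eps_min, dt_limit = dt_max)
  class(state) <- "fdtd_simulation"
  state
}

#' @export
print.fdtd_simulation <- function(x, ...) {
  cat(sprintf("TMz FDTD simulation: %d x %d cells (%d interior + %d CPML), dt = %g ps\n",
              x$N, x$N, x$N - 2 * x$offset, x$offset, x$scfg$dt * 1e12))
  cat(sprintf("  eps_min = %.3g (Courant limit %.3g ps)\n", x$eps_min,
              x$dt_limit * 1e12))
  invisible(x)
}

# Antenna interior indices mapped into the padded grid, 0-based for C++.
tx_rx_cells <- function(sim) {
  idx <- sim$array$grid_indices + sim$offset - 1L
  storage.mode(idx) <- "integer"
  idx
}

#' Advance a simulation by one (or more) leapfrog steps
#'
#' One step updates H from the curl of Ez, then Ez from the curl of H with
#' the loss coefficients, adds the source value to Ez at the transmitter
#' cell ("soft" source), and advances the absorbing-layer accumulators.
#' Intended for inspection and testing; production runs use
#' [run_single_tx()].
#'
#' @param sim An `fdtd_simulation`.
#' @param source_value Source value(s) added to Ez, one per step.
#' @param tx_cell `c(i, j)` interior-grid cell (1-based); defaults to the
#'   first antenna.
#' @return The simulation with updated `fields`.
#' @export
fdtd_step <- function(sim, source_value = 0, tx_cell = NULL) {
  if (is.null(tx_cell)) tx_cell <- sim$array$grid_indices[1, ]
  tx <- as.integer(tx_cell) + sim$offset - 1L
  res <- fdtd_core_cpp(sim$eps_r, sim$sigma, sim$scfg$dt, sim$scfg$dx,
                       sim$offset, sim$scfg$pml_order,
                       sim$scfg$pml_target_reflection,
                       sim$scfg$pml_kappa_max, sim$scfg$pml_alpha_max,
                       sim$dcfg$matching_eps,
                       as.numeric(source_value), tx[1], tx[2],
                       tx_rx_cells(sim),
                       FALSE, TRUE, sim$fields$Ez, sim$fields$Hx,
                       sim$fields$Hy)
  sim$fields <- list(Ez = res$Ez, Hx = res$Hx, Hy = res$Hy)
  sim
}

#' Run one transmitter and record all receivers
#'
#' Excites antenna `tx_index` with the pulse and records Ez at every
#' antenna cell (including the transmitter's own) at every time step.
#'
#' @param sim An `fdtd_simulation`.
#' @param tx_index Transmitter index, 1-based.
#' @param pulse A [design_pulse()] waveform (its `dt` must equal the solver
#'   `dt`).
#' @param record_energy Also record the staggered discrete field energy per
#'   step (for diagnostics).
#' @return Matrix `n_antennas x n_steps` of received Ez samples; when
#'   `record_energy` is set, the energy series is attached as attribute
#'   `"energy"`.
#' @export
run_single_tx <- function(sim, tx_index, pulse, record_energy = FALSE) {
  if (tx_index < 1 || tx_index > sim$array$n_antennas)
    stop("tx_index out of range", call. = FALSE)
  if (abs(pulse$dt - sim$scfg$dt) > 1e-18)
    stop("pulse dt does not match solver dt", call. = FALSE)
  cells <- tx_rx_cells(sim)
  res <- fdtd_core_cpp(sim$eps_r, sim$sigma, sim$scfg$dt, sim$scfg$dx,
                       sim$offset, sim$scfg$pml_order,
                       sim$scfg$pml_target_reflection,
                       sim$scfg$pml_kappa_max, sim$scfg$pml_alpha_max,
                       sim$dcfg$matching_eps,
                       pulse$samples, cells[tx_index, 1], cells[tx_index, 2],
                       cells, record_energy, FALSE)
  traces <- res$traces
  if (record_energy) attr(traces, "energy") <- as.numeric(res$energy)
  traces
}

#' Run the full multistatic acquisition
#'
#' Loops [run_single_tx()] over all antennas, producing the raw signal
#' tensor with axes (transmitter, receiver, time). Deterministic given its
#' inputs.
#'
#' @param phantom A `phantom_case`.
#' @param array An [antenna_array()].
#' @param scfg A [solver_config()].
#' @param dcfg The matching [domain_config()].
#' @param pulse Optional pulse; defaults to [design_pulse()] at the solver
#'   band and time step.
#' @param progress Print per-transmitter progress.
#' @return 3D array `n_antennas x n_antennas x n_steps` of class
#'   `signal_tensor`.
#' @export
run_multistatic <- function(phantom, array, scfg, dcfg, pulse = NULL,
                            progress = FALSE) {
  if (is.null(pulse))
    pulse <- design_pulse(scfg$band_low, scfg$band_high, scfg$dt,
                          scfg$n_steps)
  sim <- build_simulation(phantom, array, scfg, dcfg)
  na <- array$n_antennas
  tens <- array(0, dim = c(na, na, scfg$n_steps))
  for (tx in seq_len(na)) {
    if (progress) message(sprintf("transmitter %d/%d", tx, na))
    tr <- tryCatch(run_single_tx(sim, tx, pulse),
                   error = function(e)
                     stop(sprintf("transmitter %d: %s", tx,
                                  conditionMessage(e)), call. = FALSE))
    tens[tx, , ] <- tr
  }
  class(tens) <- c("signal_tensor", class(tens))
  tens
}

#' Scattered-field calibration
#'
#' Subtracts the incident field recorded in an empty domain (pure matching
#' medium, no objects) from a total-field signal tensor, yielding the
#' scattered field.
#'
#' @param tensor Total-field `signal_tensor`.
#' @param array,scfg,dcfg Acquisition configuration used for `tensor`.
#' @param pulse Pulse used for `tensor` (default: solver-band pulse).
#' @return Scattered-field tensor of the same shape.
#' @export
scattered_field <- function(tensor, array, scfg, dcfg, pulse = NULL) {
  n <- grid_cells(dcfg)
  empty <- list(case_id = "empty",
                eps_map = matrix(dcfg$matching_eps, n, n),
                sigma_map = matrix(dcfg$matching_sigma, n, n))
  inc <- run_multistatic(empty, array, scfg, dcfg, pulse = pulse)
  out <- unclass(tensor) - unclass(inc)
  class(out) <- c("signal_tensor", class(out))
  out
}

#' Analytic line-source field in a homogeneous medium
#'
#' Frequency-domain reference solution for the field radiated by the
#' discrete soft source in an unbounded homogeneous lossless medium,
#' evaluated at distance `r` and inverse-transformed to the solver's time
#' grid. The soft source adding `s[n]` to Ez each step is equivalent to a
#' line current `I(t) = -eps * s(t) * dx^2 / dt` (cell cross-section
#' `dx^2`), and the radiated field of a 2D line current is
#' `Ez(w) = -(w mu0 / 4) I(w) H0_2(k r)` with `H0_2` the Hankel function of
#' the second kind. Used as an independent oracle for the solver.
#'
#' @param pulse A [design_pulse()] waveform.
#' @param r Source-receiver distance, m.
#' @param eps_r Relative permittivity of the medium.
#' @param dx Cell size, m.
#' @param n_steps Number of output samples.
#' @return Numeric vector: Ez at the receiver on the solver time grid.
#' @export
analytic_line_source <- function(pulse, r, eps_r, dx, n_steps) {
  dt <- pulse$dt
  nfft <- 2^ceiling(log2(max(n_steps, length(pulse$samples)) * 4))
  s <- c(pulse$samples, numeric(nfft - length(pulse$samples)))
  S <- fft(s)
  f <- (seq_len(nfft) - 1) / (nfft * dt)
  f[f >= 1 / (2 * dt)] <- f[f >= 1 / (2 * dt)] - 1 / dt  # signed frequencies
  w <- 2 * pi * f
  eps <- eps_r * .eps0
  # current spectrum. The source sample of index n acts during the update to
  # time (n+1) dt, i.e. at (n+1/2) dt, and the receiver sample of index n is
  # the field at (n+1) dt: the net alignment is a half-sample advance.
  Iw <- -eps * S * dx^2 / dt * exp(+1i * w * dt / 2)
  k <- abs(w) * sqrt(eps_r) / .c0
  kr <- k * r
  H02 <- function(x) besselJ(x, 0) - 1i * besselY(x, 0)
  Ez <- complex(length.out = nfft)
  pos <- which(f > 0)
  Ez[pos] <- -(w[pos] * .mu0 / 4) * Iw[pos] * H02(kr[pos])
  neg <- which(f < 0)
  # Hermitian symmetry for a real time series
  Ez[neg] <- Conj(Ez[nfft + 2 - neg])
  Re(fft(Ez, inverse = TRUE) / nfft)[seq_len(n_steps)]
}
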