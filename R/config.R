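#' Imaging-domain configuration
#'
#' Describes the square simulation domain, the circular imaging region, the
#' antenna ring, and the ranges from which random phantoms draw their
#' geometry and dielectric properties. Defaults reproduce the reference
#' acquisition setup: a 500 mm x 500 mm domain meshed at 2 mm, a 130 mm
#' imaging circle, 16 antennas on a 150 mm ring, relative permittivity in
#' \[10, 80\] and conductivity in \[0.2, 2.5\] S/m (spanning most human
#' tissues), and a matching-medium background of (40, 0.1 S/m).
#'
#' @param domain_size Side of the square domain, mm.
#' @param cell_size Grid cell size, mm. `domain_size / cell_size` must be a
#'   positive integer.
#' @param imaging_radius Radius of the circular imaging region, mm. All
#'   phantom objects are confined to this circle.
#' @param antenna_radius Radius of the antenna ring, mm. Must satisfy
#'   `imaging_radius < antenna_radius < domain_size / 2`.
#' @param n_antennas Number of antennas, evenly spaced in angle.
#' @param eps_range Closed interval for relative permittivity values.
#' @param sigma_range Closed interval for conductivity values, S/m.
#' @param matching_eps,matching_sigma Background (matching-medium) relative
#'   permittivity and conductivity.
#' @param n_shapes_range Integer interval for the number of superimposed
#'   shapes per phantom.
#' @param axis_range Interval for full ellipse/polygon axis lengths, mm.
#' @param polygon_edges_range Integer interval for polygon edge counts.
#' @param label_size Side of the square ground-truth label image, pixels.
#' @return An object of class `domain_config`.
#' @export
domain_config <- function(domain_size = 500, cell_size = 2,
                          imaging_radius = 130, antenna_radius = 150,
                          n_antennas = 16,
                          eps_range = c(10, 80), sigma_range = c(0.2, 2.5),
                          matching_eps = 40, matching_sigma = 0.1,
                          n_shapes_range = c(6, 24), axis_range = c(50, 120),
                          polygon_edges_range = c(3, 6), label_size = 256) {
  cfg <- list(domain_size = domain_size, cell_size = cell_size,
              imaging_radius = imaging_radius, antenna_radius = antenna_radius,
              n_antennas = as.integer(n_antennas),
              eps_range = eps_range, sigma_range = sigma_range,
              matching_eps = matching_eps, matching_sigma = matching_sigma,
              n_shapes_range = as.integer(n_shapes_range),
              axis_range = axis_range,
              polygon_edges_range = as.integer(polygon_edges_range),
              label_size = as.integer(label_size))
  class(cfg) <- "domain_config"
  validate_domain_config(cfg)
  cfg
}

validate_domain_config <- function(cfg) {
  n <- cfg$domain_size / cfg$cell_size
  if (cfg$cell_size <= 0 || abs(n - round(n)) > 1e-9 || n < 1)
    stop("domain_size / cell_size must be a positive integer", call. = FALSE)
  if (!(cfg$imaging_radius < cfg$antenna_radius &&
        cfg$antenna_radius < cfg$domain_size / 2))
    stop("require imaging_radius < antenna_radius < domain_size/2",
         call. = FALSE)
  for (nm in c("eps_range", "sigma_range", "axis_range",
               "n_shapes_range", "polygon_edges_range")) {
    iv <- cfg[[nm]]
    if (length(iv) != 2 || any(!is.finite(iv)) || iv[1] > iv[2])
      stop(sprintf("%s must be a non-empty interval (lo <= hi)", nm),
           call. = FALSE)
  }
  if (cfg$polygon_edges_range[1] < 3)
    stop("polygons need at least 3 edges", call. = FALSE)
  if (cfg$n_antennas < 1) stop("n_antennas must be >= 1", call. = FALSE)
  if (cfg$label_size < 2) stop("label_size must be >= 2", call. = FALSE)
  invisible(cfg)
}

#' Number of grid cells per side of the simulation grid
#' @param cfg A `domain_config`.
#' @return Integer cell count (250 at defaults).
#' @export
grid_cells <- function(cfg) as.integer(round(cfg$domain_size / cfg$cell_size))

#' @export
print.domain_config <- function(x, ...) {
  cat("Imaging domain configuration\n")
  cat(sprintf("  domain: %g mm x %g mm, %d x %d cells of %g mm\n",
              x$domain_size, x$domain_size, grid_cells(x), grid_cells(x),
              x$cell_size))
  cat(sprintf("  imaging circle radius: %g mm; %d antennas at %g mm\n",
              x$imaging_radius, x$n_antennas, x$antenna_radius))
  cat(sprintf("  eps in [%g, %g], sigma in [%g, %g] S/m; background (%g, %g)\n",
              x$eps_range[1], x$eps_range[2], x$sigma_range[1],
              x$sigma_range[2], x$matching_eps, x$matching_sigma))
  cat(sprintf("  shapes per phantom: %d-%d, axes %g-%g mm, polygon edges %d-%d\n",
              x$n_shapes_range[1], x$n_shapes_range[2], x$axis_range[1],
              x$axis_range[2], x$polygon_edges_range[1],
              x$polygon_edges_range[2]))
  invisible(x)
}

#' FDTD solver configuration
#'
#' Time stepping, mesh, absorbing-boundary, and excitation-band settings for
#' the 2D TMz solver. Defaults follow the reference acquisition: a 4.72 ps
#' time step for 5000 steps (23.6 ns total) on a 2 mm mesh, with a 16-cell
#' convolutional perfectly matched layer (CPML) and a 0.5-2 GHz excitation
#' band.
#'
#' The explicit leapfrog scheme is stable only if
#' `dt <= dx * sqrt(eps_min) / (c0 * sqrt(2))`, where `eps_min` is the
#' minimum relative permittivity anywhere on the grid. This is checked at
#' run time by [build_simulation()]: the default 4.72 ps step is admissible
#' for the matching-medium-filled grids produced here (eps_min = 10 gives a
#' 14.9 ps limit) but not for grids containing vacuum (limit 4.714 ps).
#'
#' @param dt Time step, s.
#' @param n_steps Number of time steps.
#' @param dx Cell size, m. Must agree with the domain configuration.
#' @param pml_cells CPML thickness in cells.
#' @param pml_order Polynomial grading order of the CPML conductivity.
#' @param pml_target_reflection Design normal-incidence reflection.
#' @param pml_kappa_max Maximum coordinate-stretching factor.
#' @param pml_alpha_max Complex-frequency-shift parameter, S/m.
#' @param band_low,band_high Excitation band edges (-10 dB points), Hz.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = 4.72e-12, n_steps = 5000, dx = 2e-3,
                          pml_cells = 16, pml_order = 3,
                          pml_target_reflection = 1e-6,
                          pml_kappa_max = 1, pml_alpha_max = 0,
                          band_low = 0.5e9, band_high = 2e9) {
  cfg <- list(dt = dt, n_steps = as.integer(n_steps), dx = dx,
              pml_cells = as.integer(pml_cells), pml_order = pml_order,
              pml_target_reflection = pml_target_reflection,
              pml_kappa_max = pml_kappa_max, pml_alpha_max = pml_alpha_max,
              band_low = band_low, band_high = band_high)
  class(cfg) <- "solver_config"
  if (dt <= 0 || dx <= 0 || cfg$n_steps < 1)
    stop("dt, dx and n_steps must be positive", call. = FALSE)
  if (!(band_low > 0 && band_low < band_high))
    stop("require 0 < band_low < band_high", call. = FALSE)
  if (band_high >= 1 / (2 * dt))
    stop("band_high violates the Nyquist limit 1/(2 dt)", call. = FALSE)
  cfg
}

#' @export
print.solver_config <- function(x, ...) {
  cat("FDTD solver configuration\n")
  cat(sprintf("  dt = %g ps x %d steps = %g ns; dx = %g mm\n",
              x$dt * 1e12, x$n_steps, x$dt * x$n_steps * 1e9, x$dx * 1e3))
  cat(sprintf("  CPML: %d cells, order %g, target reflection %g\n",
              x$pml_cells, x$pml_order, x$pml_target_reflection))
  cat(sprintf("  band: %g-%g GHz\n", x$band_low / 1e9, x$band_high / 1e9))
  invisible(x)
}

#' Courant stability limit of the 2D scheme
#'
#' @param eps_min Minimum relative permittivity on the grid.
#' @param dx Cell size, m.
#' @return Largest admissible time step, s.
#' @export
courant_limit <- function(eps_min, dx) dx * sqrt(eps_min) / (.c0 * sqrt(2))

#' Reconstruction-network configuration
#'
#' Architecture of the encoder-decoder (U-net style) network. Defaults give
#' a depth-5 network with two 5x5 convolutions (stride 1, same padding,
#' rectified-linear activations) per level, 2x2 max-pooling between encoder
#' levels, channel widths 8-128, 2x2 stride-2 transposed convolutions in the
#' decoder with skip concatenation, and a final 1x1 convolution to one
#' channel. A 256x256 input then reaches a 16x16 bottleneck with 128
#' channels.
#'
#' @param input_size Input side length, pixels; must be divisible by
#'   `2^(depth - 1)`.
#' @param depth Number of resolution levels.
#' @param convs_per_level Convolutions per level.
#' @param kernel_size Convolution kernel side, pixels.
#' @param encoder_channels Channel width per level, length `depth`.
#' @param pool_size,upconv_size,upconv_stride Pooling / transposed-conv
#'   geometry (only 2/2/2 is implemented).
#' @param output_channels Output channels (1 = permittivity map).
#' @param skip_connections Concatenate encoder features into the decoder.
#' @return An object of class `net_config`.
#' @export
net_config <- function(input_size = 256, depth = 5, convs_per_level = 2,
                       kernel_size = 5,
                       encoder_channels = c(8, 16, 32, 64, 128),
                       pool_size = 2, upconv_size = 2, upconv_stride = 2,
                       output_channels = 1, skip_connections = TRUE) {
  cfg <- list(input_size = as.integer(input_size), depth = as.integer(depth),
              convs_per_level = as.integer(convs_per_level),
              kernel_size = as.integer(kernel_size),
              encoder_channels = as.integer(encoder_channels),
              pool_size = as.integer(pool_size),
              upconv_size = as.integer(upconv_size),
              upconv_stride = as.integer(upconv_stride),
              output_channels = as.integer(output_channels),
              skip_connections = isTRUE(skip_connections))
  class(cfg) <- "net_config"
  if (length(cfg$encoder_channels) != cfg$depth)
    stop("encoder_channels must have one entry per level", call. = FALSE)
  if (cfg$pool_size != 2 || cfg$upconv_size != 2 || cfg$upconv_stride != 2)
    stop("only 2x2 pooling and 2x2 stride-2 transposed convolutions are supported",
         call. = FALSE)
  if (cfg$input_size %% 2^(cfg$depth - 1) != 0)
    stop(sprintf("input_size must be divisible by 2^(depth-1) = %d",
                 2^(cfg$depth - 1)), call. = FALSE)
  if (cfg$kernel_size %% 2 != 1)
    stop("kernel_size must be odd (same-size padding)", call. = FALSE)
  cfg
}

#' Encoder spatial sizes per level
#' @param cfg A `net_config`.
#' @return Integer vector of length `depth`; at defaults
#'   `c(256, 128, 64, 32, 16)`.
#' @export
encoder_sizes <- function(cfg) {
  as.integer(cfg$input_size / 2^(seq_len(cfg$depth) - 1))
}

#' Training configuration
#'
#' Optimization settings for the reconstruction network: adaptive-moment
#' (Adam) optimizer with learning rate 5e-4, mean-squared-error loss, batch
#' size 32. Labels are mapped affinely from the permittivity design range
#' onto \[0, 1\] for training and inverted at prediction time.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Cases per optimization step.
#' @param loss Loss function; only `"mse"`.
#' @param optimizer Only `"adam"`.
#' @param epochs Passes over the training set (used when `steps` is not
#'   given to [train_unet()]).
#' @param seed Integer seed for parameter initialization and batch sampling.
#' @param label_scaling `c(offset, scale)`: training target is
#'   `(eps - offset) / scale`. Default maps \[10, 80\] onto \[0, 1\].
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and
#'   stabilizer.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, batch_size = 32,
                         loss = "mse", optimizer = "adam", epochs = 1,
                         seed = 1, label_scaling = c(offset = 10, scale = 70),
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8) {
  loss <- match.arg(loss, "mse")
  optimizer <- match.arg(optimizer, "adam")
  cfg <- list(learning_rate = learning_rate,
              batch_size = as.integer(batch_size), loss = loss,
              optimizer = optimizer, epochs = as.integer(epochs),
              seed = as.integer(seed),
              label_scaling = c(offset = unname(label_scaling[1]),
                                scale = unname(label_scaling[2])),
              adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
              adam_eps = adam_eps)
  class(cfg) <- "train_config"
  if (cfg$batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (cfg$label_scaling["scale"] == 0)
    stop("label_scaling scale must be nonzero", call. = FALSE)
  cfg
}

# Stable hash of a configuration (or any plain list): md5 of canonical JSON.
#' Configuration hash
#' @param cfg Any configuration object or plain list.
#' @return 32-character md5 digest string.
#' @export
config_hash <- function(cfg) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  js <- jsonlite::toJSON(strip(cfg), auto_unbox = TRUE, digits = 15)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}
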