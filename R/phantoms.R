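#' Sample one random shape
#'
#' Draws a random ellipse or convex polygon with random pose and dielectric
#' values, using the current RNG stream. Kind is chosen uniformly; the full
#' major and minor axes are uniform on `cfg$axis_range`; the rotation is
#' uniform on \[0, 360) degrees; polygon edge counts are uniform on
#' `cfg$polygon_edges_range`; permittivity and conductivity are independent
#' uniform draws from `cfg$eps_range` and `cfg$sigma_range`. The center is
#' uniform over the imaging disc, so every shape intersects the imaging
#' circle.
#'
#' Polygon vertices are placed on the shape's ellipse at sorted uniform
#' angles, giving convex polygons whose extent is controlled by the same
#' axis bounds as ellipses.
#'
#' @param cfg A [domain_config()].
#' @return An object of class `shape_spec`.
#' @export
sample_shape <- function(cfg) {
  validate_domain_config(cfg)
  kind <- if (runif(1) < 0.5) "ellipse" else "polygon"
  r <- cfg$imaging_radius * sqrt(runif(1))
  th <- runif(1, 0, 2 * pi)
  axes <- sort(runif(2, cfg$axis_range[1], cfg$axis_range[2]),
               decreasing = TRUE)
  n_edges <- NA_integer_
  vertex_angles <- NULL
  if (kind == "polygon") {
    er <- cfg$polygon_edges_range
    n_edges <- sample(seq(er[1], er[2]), 1L)
    vertex_angles <- sort(runif(n_edges, 0, 360))
  }
  shape <- list(kind = kind,
                center = c(x = r * cos(th), y = r * sin(th)),
                major_axis = axes[1], minor_axis = axes[2],
                n_edges = n_edges, vertex_angles = vertex_angles,
                rotation = runif(1, 0, 360),
                eps_value = runif(1, cfg$eps_range[1], cfg$eps_range[2]),
                sigma_value = runif(1, cfg$sigma_range[1], cfg$sigma_range[2]))
  class(shape) <- "shape_spec"
  shape
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf("%s at (%.1f, %.1f) mm, axes %.1f x %.1f mm, rot %.1f deg",
              x$kind, x$center[1], x$center[2], x$major_axis, x$minor_axis,
              x$rotation))
  if (x$kind == "polygon") cat(sprintf(", %d edges", x$n_edges))
  cat(sprintf("; eps %.2f, sigma %.3f S/m\n", x$eps_value, x$sigma_value))
  invisible(x)
}

# Vertices (mm, domain frame) of a polygon shape.
polygon_vertices <- function(shape) {
  a <- shape$vertex_angles * pi / 180
  p <- rbind(shape$major_axis / 2 * cos(a), shape$minor_axis / 2 * sin(a))
  rot <- shape$rotation * pi / 180
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  v <- R %*% p
  v[1, ] <- v[1, ] + shape$center[1]
  v[2, ] <- v[2, ] + shape$center[2]
  v
}

# Coordinates (mm) of cell centers for a `resolution`-cell raster of the
# square [-L/2, L/2]. Row index i corresponds to x, column j to y.
raster_axis <- function(domain_size, resolution) {
  -domain_size / 2 + (seq_len(resolution) - 0.5) * domain_size / resolution
}

#' Rasterize a shape to a binary mask
#'
#' A cell is inside the mask iff its center lies inside the (rotated) shape
#' and inside the imaging circle. Ellipse membership uses the standard
#' quadratic form in the shape frame; polygon membership uses an even-odd
#' ray-crossing test.
#'
#' @param shape A `shape_spec`.
#' @param cfg A [domain_config()].
#' @param resolution Cells per side of the raster (>= 2).
#' @return Logical `resolution x resolution` matrix (rows = x, cols = y).
#' @export
rasterize_shape <- function(shape, cfg, resolution = grid_cells(cfg)) {
  if (resolution < 2) stop("resolution must be >= 2", call. = FALSE)
  ax <- raster_axis(cfg$domain_size, resolution)
  X <- matrix(ax, resolution, resolution)
  Y <- matrix(ax, resolution, resolution, byrow = TRUE)
  inside_circle <- X^2 + Y^2 <= cfg$imaging_radius^2
  if (shape$kind == "ellipse") {
    rot <- shape$rotation * pi / 180
    dx <- X - shape$center[1]; dy <- Y - shape$center[2]
    u <- cos(rot) * dx + sin(rot) * dy
    v <- -sin(rot) * dx + cos(rot) * dy
    inside <- (2 * u / shape$major_axis)^2 + (2 * v / shape$minor_axis)^2 <= 1
  } else {
    v <- polygon_vertices(shape)
    n <- ncol(v)
    # Degenerate (collinear) polygons have (near-)zero area.
    area <- 0.5 * abs(sum(v[1, ] * v[2, c(2:n, 1)] - v[1, c(2:n, 1)] * v[2, ]))
    if (area < 1e-9 * shape$major_axis^2)
      stop("degenerate polygon: vertices are collinear", call. = FALSE)
    inside <- matrix(FALSE, resolution, resolution)
    px <- as.vector(X); py <- as.vector(Y)
    crossings <- integer(length(px))
    for (e in seq_len(n)) {
      x1 <- v[1, e]; y1 <- v[2, e]
      x2 <- v[1, e %% n + 1]; y2 <- v[2, e %% n + 1]
      hit <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      crossings <- crossings + hit
    }
    inside <- matrix(crossings %% 2 == 1, resolution, resolution)
  }
  inside & inside_circle
}

#' Compose shapes into a phantom
#'
#' Superimposes the shapes on a matching-medium background: each shape adds
#' its `(eps_value, sigma_value)` over its mask, and the covered cells are
#' then affinely rescaled (per case, per property) so the object-support
#' minimum and maximum map onto the configured dielectric ranges. When the
#' support is constant (e.g. a single shape), the value is kept, clipped
#' into range. Background cells keep the matching-medium values exactly.
#' The ground-truth label is rendered at `cfg$label_size` from the same
#' analytic shape set (nearest-neighbour, not resampled from the solver
#' grid) with the same per-case rescale.
#'
#' @param shapes Nonempty list of `shape_spec`.
#' @param cfg A [domain_config()].
#' @param case_id Identifier stored on the case.
#' @return An object of class `phantom_case` with fields `case_id`, `shapes`,
#'   `eps_map`, `sigma_map` (solver grid), `label_eps` (label raster) and
#'   `group_index` (number of superimposed shapes).
#' @export
compose_phantom <- function(shapes, cfg, case_id = "case") {
  if (length(shapes) == 0) stop("empty shape list", call. = FALSE)
  n <- grid_cells(cfg)
  masks <- lapply(shapes, rasterize_shape, cfg = cfg, resolution = n)
  support <- Reduce(`|`, masks)
  if (!any(support))
    stop("degenerate case: all shapes clipped away by the imaging circle",
         call. = FALSE)

  raw <- function(masks, values, resolution) {
    m <- matrix(0, resolution, resolution)
    for (k in seq_along(masks)) m[masks[[k]]] <- m[masks[[k]]] + values[k]
    m
  }
  eps_vals <- vapply(shapes, `[[`, numeric(1), "eps_value")
  sig_vals <- vapply(shapes, `[[`, numeric(1), "sigma_value")
  raw_eps <- raw(masks, eps_vals, n)
  raw_sig <- raw(masks, sig_vals, n)

  # Per-case affine rescale of support cells into the target interval,
  # computed on the solver grid and reused for the label raster.
  rescale_params <- function(vals, range) {
    lo <- min(vals); hi <- max(vals)
    if (hi > lo) {
      a <- (range[2] - range[1]) / (hi - lo)
      c(a = a, b = range[1] - a * lo)
    } else c(a = 1, b = 0)  # identity; clipped into range on application
  }
  pe <- rescale_params(raw_eps[support], cfg$eps_range)
  ps <- rescale_params(raw_sig[support], cfg$sigma_range)
  apply_rescale <- function(m, sup, p, range, bg) {
    out <- matrix(bg, nrow(m), ncol(m))
    out[sup] <- pmin(pmax(p["a"] * m[sup] + p["b"], range[1]), range[2])
    out
  }
  eps_map <- apply_rescale(raw_eps, support, pe, cfg$eps_range, cfg$matching_eps)
  sigma_map <- apply_rescale(raw_sig, support, ps, cfg$sigma_range,
                             cfg$matching_sigma)

  lab_masks <- lapply(shapes, rasterize_shape, cfg = cfg,
                      resolution = cfg$label_size)
  lab_support <- Reduce(`|`, lab_masks)
  raw_lab <- raw(lab_masks, eps_vals, cfg$label_size)
  label_eps <- apply_rescale(raw_lab, lab_support, pe, cfg$eps_range,
                             cfg$matching_eps)

  case <- list(case_id = case_id, shapes = shapes, eps_map = eps_map,
               sigma_map = sigma_map, label_eps = label_eps,
               group_index = length(shapes))
  class(case) <- "phantom_case"
  case
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("Phantom case '%s': %d shapes, eps in [%.2f, %.2f], sigma in [%.3f, %.3f] S/m\n",
              x$case_id, length(x$shapes), min(x$eps_map), max(x$eps_map),
              min(x$sigma_map), max(x$sigma_map)))
  cat(sprintf("  maps %d x %d, label %d x %d\n", nrow(x$eps_map),
              ncol(x$eps_map), nrow(x$label_eps), ncol(x$label_eps)))
  invisible(x)
}

# Shape counts available to group g of n_groups, banding the configured
# n_shapes_range into near-equal consecutive bands.
group_shape_counts <- function(cfg, g, n_groups = 10) {
  counts <- seq(cfg$n_shapes_range[1], cfg$n_shapes_range[2])
  bands <- split(counts, ceiling(seq_along(counts) / (length(counts) / n_groups)))
  bands[[min(g, length(bands))]]
}

#' Generate a database of random phantom cases
#'
#' Cases are partitioned into `n_groups` (default 10) equal groups; group g
#' draws its per-case shape count from the g-th band of the configured
#' range, so the superimposed-shape count increases from the lower to the
#' upper bound across groups. Generation is fully reproducible from `seed`.
#'
#' With `grouped = FALSE`, every case draws its shape count uniformly from
#' `shape_count_range` (defaulting to `cfg$n_shapes_range`); this is the
#' simple-object mode used for small validation sets (e.g. 1-2 shapes).
#'
#' @param n_cases Number of cases (>= 0). With `grouped = TRUE` it must be
#'   divisible by `n_groups`.
#' @param cfg A [domain_config()].
#' @param seed Integer seed.
#' @param grouped Partition into shape-count groups.
#' @param n_groups Number of groups.
#' @param shape_count_range Integer interval overriding `cfg$n_shapes_range`
#'   when `grouped = FALSE`.
#' @param callback Optional `function(case)` invoked on each case as it is
#'   generated (e.g. [save_case()]); when supplied, cases are not
#'   accumulated in memory and the case ids are returned instead.
#' @return List of `phantom_case` (or character vector of ids when
#'   `callback` is used).
#' @export
generate_database <- function(n_cases, cfg, seed, grouped = TRUE,
                              n_groups = 10, shape_count_range = NULL,
                              callback = NULL) {
  validate_domain_config(cfg)
  if (n_cases < 0) stop("n_cases must be >= 0", call. = FALSE)
  if (grouped && n_cases %% n_groups != 0)
    stop(sprintf("n_cases must be divisible by the group count (%d)", n_groups),
         call. = FALSE)
  out <- if (is.null(callback)) vector("list", n_cases) else character(n_cases)
  if (n_cases == 0) return(out)
  with_seed(seed, {
    for (i in seq_len(n_cases)) {
      if (grouped) {
        g <- ceiling(i / (n_cases / n_groups))
        pool <- group_shape_counts(cfg, g, n_groups)
      } else {
        rng <- if (is.null(shape_count_range)) cfg$n_shapes_range
               else shape_count_range
        pool <- seq(rng[1], rng[2])
      }
      k <- if (length(pool) == 1) pool else sample(pool, 1L)
      shapes <- replicate(k, sample_shape(cfg), simplify = FALSE)
      case <- compose_phantom(shapes, cfg,
                              case_id = sprintf("case_%05d", i))
      if (is.null(callback)) out[[i]] <- case
      else { callback(case); out[i] <- case$case_id }
    }
  })
  out
}

#' Export a label image as PNG
#'
#' Linearly maps permittivity from the configured range to 8-bit gray and
#' writes a PNG (requires the `png` package). For visual inspection only.
#'
#' @param label Permittivity image (matrix).
#' @param path Output file.
#' @param eps_range Mapping range, default `c(10, 80)`.
#' @export
export_label_png <- function(label, path, eps_range = c(10, 80)) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export", call. = FALSE)
  g <- (label - eps_range[1]) / diff(eps_range)
  g <- pmin(pmax(g, 0), 1)
  tg <- t(g)  # image rows = y (top = +y), columns = x
  png::writePNG(tg[nrow(tg):1, , drop = FALSE], target = path)
  invisible(path)
}
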