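test_that("sampled shapes respect every configured range", {
  cfg <- domain_config()
  shapes <- emtomo:::with_seed(1,
    replicate(10000, sample_shape(cfg), simplify = FALSE))
  major <- vapply(shapes, `[[`, numeric(1), "major_axis")
  minor <- vapply(shapes, `[[`, numeric(1), "minor_axis")
  rot <- vapply(shapes, `[[`, numeric(1), "rotation")
  eps <- vapply(shapes, `[[`, numeric(1), "eps_value")
  sig <- vapply(shapes, `[[`, numeric(1), "sigma_value")
  expect_true(all(major >= 50 & major <= 120))
  expect_true(all(minor >= 50 & minor <= 120))
  expect_true(all(minor <= major))
  expect_true(all(rot >= 0 & rot < 360))
  edges <- vapply(shapes, `[[`, integer(1), "n_edges")
  polys <- !is.na(edges)
  expect_true(all(edges[polys] %in% 3:6))
  expect_true(any(polys) && any(!polys))
  # centers inside the imaging disc => every shape intersects the circle
  centers <- t(vapply(shapes, `[[`, numeric(2), "center"))
  expect_true(all(rowSums(centers^2) <= cfg$imaging_radius^2 + 1e-9))

  # dielectric draws are uniform on their ranges (KS against the uniform CDF)
  ks_eps <- suppressWarnings(
    stats::ks.test(eps, "punif", 10, 80)$statistic)
  ks_sig <- suppressWarnings(
    stats::ks.test(sig, "punif", 0.2, 2.5)$statistic)
  expect_lt(ks_eps, 0.02)
  expect_lt(ks_sig, 0.02)
})

test_that("invalid configuration ranges are a configuration error", {
  cfg <- domain_config()
  cfg$eps_range <- c(80, 10)
  expect_error(emtomo:::with_seed(1, sample_shape(cfg)), "eps_range")
})

test_that("a disc rasterizes to the analytic area and is rotation invariant", {
  cfg <- domain_config()
  circle <- structure(list(kind = "ellipse", center = c(x = 0, y = 0),
                           major_axis = 100, minor_axis = 100,
                           n_edges = NA_integer_, rotation = 0,
                           eps_value = 50, sigma_value = 1),
                      class = "shape_spec")
  m0 <- rasterize_shape(circle, cfg)
  area_cells <- sum(m0) * cfg$cell_size^2
  expect_lt(abs(area_cells - pi * 50^2) / (pi * 50^2), 0.03)
  for (rot in c(30, 123.4, 270)) {
    cr <- circle; cr$rotation <- rot
    expect_identical(rasterize_shape(cr, cfg), m0)
  }
})

test_that("shapes outside the imaging circle rasterize to nothing", {
  cfg <- domain_config()
  far <- structure(list(kind = "ellipse", center = c(x = 200, y = 0),
                        major_axis = 60, minor_axis = 50,
                        n_edges = NA_integer_, rotation = 0,
                        eps_value = 50, sigma_value = 1),
                   class = "shape_spec")
  expect_false(any(rasterize_shape(far, cfg)))
})

test_that("polygon rasterization agrees with a winding-number oracle", {
  cfg <- domain_config()
  # independent point-in-polygon test: sum of signed angles subtended
  winding_inside <- function(px, py, v) {
    n <- ncol(v)
    total <- 0
    for (e in seq_len(n)) {
      a <- c(v[1, e] - px, v[2, e] - py)
      b <- c(v[1, e %% n + 1] - px, v[2, e %% n + 1] - py)
      total <- total + atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
    }
    abs(total) > pi
  }
  shapes <- emtomo:::with_seed(3, replicate(4, {
    s <- sample_shape(cfg)
    while (s$kind != "polygon") s <- sample_shape(cfg)
    s
  }, simplify = FALSE))
  for (s in shapes) {
    mask <- rasterize_shape(s, cfg, resolution = 64)
    v <- emtomo:::polygon_vertices(s)
    ax <- emtomo:::raster_axis(cfg$domain_size, 64)
    oracle <- matrix(FALSE, 64, 64)
    for (i in 1:64) for (j in 1:64)
      oracle[i, j] <- winding_inside(ax[i], ax[j], v) &&
        ax[i]^2 + ax[j]^2 <= cfg$imaging_radius^2
    # boundary cells can differ by floating-point ties only
    expect_lt(sum(mask != oracle), 3)
  }
})

test_that("degenerate polygons raise a geometry error", {
  cfg <- domain_config()
  s <- structure(list(kind = "polygon", center = c(x = 0, y = 0),
                      major_axis = 100, minor_axis = 100,
                      n_edges = 3L, vertex_angles = c(10, 10, 10),
                      rotation = 0, eps_value = 50, sigma_value = 1),
                 class = "shape_spec")
  expect_error(rasterize_shape(s, cfg), "collinear")
})

test_that("superposition rescales into the configured intervals", {
  cfg <- domain_config()
  mk <- function(cx, eps, sig = 1) structure(
    list(kind = "ellipse", center = c(x = cx, y = 0), major_axis = 100,
         minor_axis = 80, n_edges = NA_integer_, rotation = 0,
         eps_value = eps, sigma_value = sig), class = "shape_spec")

  # single shape: support min = max, value kept exactly
  one <- compose_phantom(list(mk(0, 50)), cfg)
  sup <- one$eps_map != cfg$matching_eps
  expect_true(all(one$eps_map[sup] == 50))

  # two overlapping shapes: raw levels {20, 60, 80} -> {10, 56.67, 80}
  two <- compose_phantom(list(mk(-20, 20), mk(20, 60)), cfg)
  vals <- sort(unique(two$eps_map[two$eps_map != cfg$matching_eps]))
  expect_equal(vals, c(10, 10 + (60 - 20) * 70 / 60, 80), tolerance = 1e-12)
  lab_vals <- sort(unique(two$label_eps[two$label_eps != cfg$matching_eps]))
  expect_equal(lab_vals, vals, tolerance = 1e-12)

  # empty input and fully clipped shapes are errors
  expect_error(compose_phantom(list(), cfg), "empty")
  far <- mk(0, 50); far$center <- c(x = 225, y = 0); far$minor_axis <- 60
  expect_error(compose_phantom(list(far), cfg), "clipped")
})

test_that("generated phantoms keep values in range with exact background", {
  cfg <- domain_config()
  cases <- generate_database(10, cfg, seed = 2)
  for (case in cases) {
    sup <- case$eps_map != cfg$matching_eps
    expect_true(all(case$eps_map[sup] >= 10 - 1e-12 &
                    case$eps_map[sup] <= 80 + 1e-12))
    sup_s <- case$sigma_map != cfg$matching_sigma
    expect_true(all(case$sigma_map[sup_s] >= 0.2 - 1e-12 &
                    case$sigma_map[sup_s] <= 2.5 + 1e-12))
    # outside the imaging circle the background is exact
    ax <- emtomo:::raster_axis(cfg$domain_size, grid_cells(cfg))
    outside <- outer(ax^2, ax^2, `+`) > cfg$imaging_radius^2
    expect_true(all(case$eps_map[outside] == 40))
    expect_true(all(case$sigma_map[outside] == 0.1))
    expect_equal(dim(case$label_eps), c(256L, 256L))
  }
})

test_that("database generation is grouped, seeded, and diverse", {
  cfg <- domain_config()
  expect_length(generate_database(0, cfg, seed = 1), 0)
  expect_error(generate_database(15, cfg, seed = 1), "divisible")

  a <- generate_database(10, cfg, seed = 7)
  b <- generate_database(10, cfg, seed = 7)
  expect_identical(a, b)

  counts <- vapply(a, `[[`, integer(1), "group_index")
  # ten groups of one case each; counts drawn from increasing bands of [6,24]
  expect_true(all(counts >= 6 & counts <= 24))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 6, tolerance = 1)
  expect_gte(counts[10], 22)

  # different seeds give different labels
  c2 <- generate_database(10, cfg, seed = 8)
  for (i in seq_along(a))
    expect_false(isTRUE(all.equal(a[[i]]$label_eps, c2[[i]]$label_eps)))

  # simple-object mode uses the same code path and invariants
  simple <- generate_database(5, cfg, seed = 3, grouped = FALSE,
                              shape_count_range = c(1, 2))
  expect_true(all(vapply(simple, `[[`, integer(1), "group_index") %in% 1:2))
})
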