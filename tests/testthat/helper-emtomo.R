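# Shared fixtures for the test suite. All heavy objects are memoized in
# this environment so independent test files can reuse one computation.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# Reduced acquisition geometry used throughout the physics tests: a 250 mm
# domain (125 x 125 cells at the standard 2 mm mesh) with the antenna ring
# and imaging circle scaled accordingly.
small_domain <- function(...) {
  domain_config(domain_size = 250, imaging_radius = 60, antenna_radius = 80,
                axis_range = c(20, 60), ...)
}

small_solver <- function(n_steps = 1250, ...) {
  solver_config(n_steps = n_steps, ...)
}

# A homogeneous lossless "phantom" covering the whole grid.
homogeneous_phantom <- function(dcfg, eps_r, sigma = 0) {
  n <- grid_cells(dcfg)
  list(case_id = "homogeneous", eps_map = matrix(eps_r, n, n),
       sigma_map = matrix(sigma, n, n))
}

# Direct C++ solver invocation with explicit tx/rx cells (interior 1-based).
raw_fdtd <- function(sim, src, tx, rx, record_energy = FALSE) {
  cells <- rx + sim$offset - 1L
  storage.mode(cells) <- "integer"
  txc <- as.integer(tx) + sim$offset - 1L
  emtomo:::fdtd_core_cpp(sim$eps_r, sim$sigma, sim$scfg$dt, sim$scfg$dx,
                         sim$offset, sim$scfg$pml_order,
                         sim$scfg$pml_target_reflection,
                         sim$scfg$pml_kappa_max, sim$scfg$pml_alpha_max,
                         sim$dcfg$matching_eps, src, txc[1], txc[2], cells,
                         record_energy, FALSE)
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# Small training fixture: n synthetic (input, label) pairs at the given
# side length. Labels are simple 1-2 shape phantom label images; inputs are
# seeded random maps in [0, 1] (a pure memorization target for capacity
# tests, independent of the solver).
capacity_fixture <- function(n = 16, side = 64, seed = 11) {
  dcfg <- domain_config(domain_size = 250, imaging_radius = 60,
                        antenna_radius = 80, axis_range = c(40, 100),
                        label_size = side)
  cases <- generate_database(n, dcfg, seed = seed, grouped = FALSE,
                             shape_count_range = c(1, 2))
  withr_seed <- seed + 1000
  inputs <- emtomo:::with_seed(withr_seed, lapply(seq_len(n), function(i)
    matrix(runif(side * side), side, side)))
  list(inputs = inputs,
       labels = lapply(cases, `[[`, "label_eps"),
       dcfg = dcfg)
}

# Memoized scaled-down end-to-end dataset: simple 1-2 shape phantoms on the
# reduced grid with simulated multistatic signals; preprocessed inputs and
# labels are decimated to 32 x 32 for CPU-scale training.
e2e_dataset <- function(n = 20, seed = 5, side = 32) {
  memo(sprintf("e2e_%d_%d_%d", n, seed, side), {
    dcfg <- domain_config(domain_size = 250, imaging_radius = 60,
                          antenna_radius = 80, axis_range = c(40, 110),
                          label_size = side)
    scfg <- small_solver(n_steps = 1250)
    arr <- antenna_array(dcfg)
    cases <- generate_database(n, dcfg, seed = seed, grouped = FALSE,
                               shape_count_range = c(1, 2))
    inputs <- vector("list", n)
    for (i in seq_len(n)) {
      tens <- run_multistatic(cases[[i]], arr, scfg, dcfg)
      im <- preprocess_signals(tens, rate = 5, pad = 6)
      inputs[[i]] <- im[seq(1, 256, by = 256 / side),
                        seq(1, 256, by = 256 / side)]
    }
    list(inputs = inputs, labels = lapply(cases, `[[`, "label_eps"),
         cases = cases, dcfg = dcfg, scfg = scfg)
  })
}
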