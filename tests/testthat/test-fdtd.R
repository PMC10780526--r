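# Solver physics on the reduced 125x125 grid (250 mm domain, standard 2 mm
# mesh). Analytic references and tolerances are discussed in the methods
# vignette; agreement with the free-space oracle is grid-dispersion
# limited, so it is checked in a medium the mesh resolves across the whole
# band (eps_r = 10, >= 23 cells per wavelength).

test_that("null dynamics: zero fields and zero source stay zero", {
  dcfg <- small_domain()
  sim <- build_simulation(homogeneous_phantom(dcfg, 40, 0.1),
                          antenna_array(dcfg), small_solver(), dcfg)
  sim <- fdtd_step(sim, source_value = rep(0, 25))
  expect_true(all(sim$fields$Ez == 0))
  expect_true(all(sim$fields$Hx == 0))
  expect_true(all(sim$fields$Hy == 0))
})

test_that("one leapfrog step matches the hand-evaluated curl", {
  dcfg <- small_domain()
  scfg <- small_solver()
  sim <- build_simulation(homogeneous_phantom(dcfg, 40, 0),
                          antenna_array(dcfg), scfg, dcfg)
  ic <- 70  # padded-grid cell index (1-based), far from the boundary layer
  sim$fields$Ez[ic, ic] <- 1
  out <- fdtd_step(sim, source_value = 0)
  mu0 <- 1.25663706212e-6
  h <- scfg$dt / (mu0 * scfg$dx)
  # H changes only on the four staggered edges adjacent to the excited cell
  expect_equal(out$fields$Hx[ic, ic], h)
  expect_equal(out$fields$Hx[ic, ic - 1], -h)
  expect_equal(out$fields$Hy[ic, ic], -h)
  expect_equal(out$fields$Hy[ic - 1, ic], h)
  Hx2 <- out$fields$Hx; Hy2 <- out$fields$Hy
  Hx2[ic, c(ic - 1, ic)] <- 0; Hy2[c(ic - 1, ic), ic] <- 0
  expect_true(all(Hx2 == 0))
  expect_true(all(Hy2 == 0))
  # and the excited Ez cell relaxes by the discrete curl of that H
  expect_equal(out$fields$Ez[ic, ic],
               1 + sim$Cb[ic, ic] * (-4 * h), tolerance = 1e-14)
})

test_that("equidistant receivers in a homogeneous medium see identical traces", {
  dcfg <- small_domain()
  scfg <- small_solver(n_steps = 700)
  sim <- build_simulation(homogeneous_phantom(dcfg, 40, 0.1),
                          antenna_array(dcfg), scfg, dcfg)
  p <- design_pulse(scfg$band_low, scfg$band_high, scfg$dt, scfg$n_steps)
  n <- grid_cells(dcfg)
  c0 <- (n + 1) %/% 2  # odd-sized padded grid: exact symmetry center
  d <- 25
  res <- raw_fdtd(sim, p$samples, c(c0, c0),
                  rbind(c(c0 + d, c0), c(c0 - d, c0),
                        c(c0, c0 + d), c(c0, c0 - d)))
  for (k in 2:4)
    expect_lt(rel_l2(res$traces[k, ], res$traces[1, ]), 1e-12)
})

test_that("a lossy medium attenuates the received pulse", {
  dcfg <- small_domain()
  scfg <- small_solver(n_steps = 700)
  p <- design_pulse(scfg$band_low, scfg$band_high, scfg$dt, scfg$n_steps)
  n <- grid_cells(dcfg)
  c0 <- (n + 1) %/% 2
  peaks <- sapply(c(0, 0.1), function(sig) {
    sim <- build_simulation(homogeneous_phantom(dcfg, 40, sig),
                            antenna_array(dcfg), scfg, dcfg)
    max(abs(raw_fdtd(sim, p$samples, c(c0, c0),
                     rbind(c(c0 + 25, c0)))$traces[1, ]))
  })
  expect_lt(peaks[2], peaks[1])
})

test_that("the homogeneous-medium trace matches the analytic line-source field", {
  dcfg <- small_domain()
  dcfg$matching_eps <- 10; dcfg$matching_sigma <- 0
  scfg <- small_solver(n_steps = 2500)
  sim <- build_simulation(homogeneous_phantom(dcfg, 10, 0),
                          antenna_array(dcfg), scfg, dcfg)
  p <- design_pulse(scfg$band_low, scfg$band_high, scfg$dt, scfg$n_steps)
  n <- grid_cells(dcfg)
  c0 <- (n + 1) %/% 2
  for (d in c(15, 25)) {
    num <- raw_fdtd(sim, p$samples, c(c0, c0),
                    rbind(c(c0 + d, c0)))$traces[1, ]
    ana <- analytic_line_source(p, d * scfg$dx, 10, scfg$dx, scfg$n_steps)
    expect_lt(rel_l2(num, ana), 0.02)
  }
})

test_that("the multistatic tensor is reciprocal on an arbitrary phantom", {
  dat <- memo("recip", {
    dcfg <- small_domain()
    scfg <- small_solver(n_steps = 1000)
    case <- generate_database(1, dcfg, seed = 21, grouped = FALSE,
                              shape_count_range = c(3, 3))[[1]]
    sim <- build_simulation(case, antenna_array(dcfg), scfg, dcfg)
    p <- design_pulse(scfg$band_low, scfg$band_high, scfg$dt, scfg$n_steps)
    list(a = run_single_tx(sim, 1, p), b = run_single_tx(sim, 6, p))
  })
  expect_lt(rel_l2(dat$a[6, ], dat$b[1, ]), 0.01)
})

test_that("lossless closed-region energy is conserved to rounding", {
  dcfg <- small_domain()
  scfg <- small_solver(n_steps = 700, pml_cells = 0,
                       band_low = 1e9, band_high = 4e9)
  sim <- build_simulation(homogeneous_phantom(dcfg, 40, 0),
                          antenna_array(dcfg), scfg, dcfg)
  p <- design_pulse(1e9, 4e9, scfg$dt, scfg$n_steps)
  n <- grid_cells(dcfg)
  c0 <- (n + 1) %/% 2
  res <- raw_fdtd(sim, p$samples, c(c0, c0), rbind(c(c0 + 10, c0)),
                  record_energy = TRUE)
  en <- res$energy
  # after the source has decayed (> delay + 4.5 tau) the staggered discrete
  # energy of the lossless PEC-closed region is a constant of the motion
  i0 <- ceiling((p$delay + 4.5 * p$tau) / scfg$dt) + 10
  window <- en[i0:length(en)]
  drift <- abs(diff(window)) / max(window)
  expect_lt(max(drift), 1e-6)
  expect_gt(max(window), 0)
})

test_that("the absorbing layer returns less than -60 dB of incident energy", {
  dcfg_small <- small_domain()
  dcfg_big <- domain_config(domain_size = 800, imaging_radius = 60,
                            antenna_radius = 80)
  scfg <- small_solver(n_steps = 3000)
  p <- design_pulse(scfg$band_low, scfg$band_high, scfg$dt, scfg$n_steps)
  run_probe <- function(dcfg) {
    dcfg$matching_sigma <- 0
    sim <- build_simulation(homogeneous_phantom(dcfg, 40, 0),
                            antenna_array(dcfg), scfg, dcfg)
    n <- grid_cells(dcfg)
    c0 <- (n + 1) %/% 2
    # probe 7 cells from the boundary of the reduced interior, on axis
    off <- 55
    raw_fdtd(sim, p$samples, c(c0, c0),
             rbind(c(c0 + off, c0)))$traces[1, ]
  }
  small <- run_probe(dcfg_small)
  reference <- run_probe(dcfg_big)  # boundary reflections arrive after the window
  expect_lt(10 * log10(sum((small - reference)^2) / sum(reference^2)), -60)
})
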