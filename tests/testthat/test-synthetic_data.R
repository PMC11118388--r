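test_that("starting orientations close the builder/analysis loop", {
  for (spec in all_system_specs()) {
    b <- build_initial_system(spec)
    p <- tmd_preset(spec$receptor)
    ts <- c(p$tilt_span$first, p$tilt_span$last)
    ds <- c(p$dhh_span$first, p$dhh_span$last)
    a1 <- fit_axis(b$frame, b$topology, "A", ts)
    a2 <- fit_axis(b$frame, b$topology, "B", ts)
    expect_equal(interhelical_distance(b$frame, b$topology, ds, ds),
                 spec$initial_dhh, tolerance = 0.05)
    expect_equal(tilt_angle(a1), spec$initial_theta, tolerance = 0.5)
    expect_equal(tilt_angle(a2), spec$initial_theta, tolerance = 0.5)
    expect_equal(crossing_angle(a1, a2), spec$initial_omega,
                 tolerance = 0.5)
  }
})

test_that("system specs carry the configured production bookkeeping", {
  specs <- all_system_specs()
  expect_length(specs, 10)
  total_us <- sum(vapply(specs, function(s)
    s$replicate_count * s$production_length_us, numeric(1)))
  expect_equal(total_us, 300)
  o1 <- system_spec("IR", "O1")
  expect_equal(o1$initial_dhh, 7.2)
  expect_equal(o1$system_size_atoms, 50822)
  expect_equal(system_spec("IGF1R", "O3")$initial_omega, 45)
  expect_equal(o1$closest_residue_gap, 2.5)
  expect_error(build_initial_system(structure(
    list(receptor = "IR", orientation = "bad", initial_dhh = 0.1,
         initial_theta = 0, initial_omega = 0, box = c(20, 20, 4)),
    class = "system_spec")), "hard-core")
})

test_that("membrane composition reports totals, charge and electroneutrality", {
  rep <- composition_report()
  expect_equal(rep$lipid_total, 1600)
  expect_equal(rep$outer_total, 800)
  expect_equal(rep$inner_total, 800)
  expect_equal(rep$net_lipid_charge, -112)   # 80 POPS + 32 POPI
  expect_equal(rep$na_required, 314)
  expect_equal(rep$cl_count, 202)
  expect_true(rep$electroneutral)
  expect_equal(rep$water_count, 15312)
  # neutral membrane: sodium balances chloride exactly
  neutral <- membrane_composition(
    outer = c(POPC = 800), inner = c(POPC = 800),
    na_count = 150, cl_count = 150)
  expect_true(composition_report(neutral)$electroneutral)
  # one leaflet emptied trips strict mode
  broken <- membrane_composition(outer = c(POPC = 0))
  expect_error(composition_report(broken), "composition error")
  expect_equal(composition_report(broken, strict = FALSE)$outer_total, 0)
})

test_that("zero temperature freezes the generator", {
  b <- build_initial_system(system_spec("IR", "O5"))
  pars <- bd_params(seed = 1, n_steps = 200, save_interval = 100,
                    temperature = 0,
                    tilt_potential = list(k = 0, theta0 = 0),
                    omega_potential = list(k = 0, omega0 = 0),
                    association_well = list(depth = 0, r0 = 1, width = 0.3))
  tr <- simulate_bd(b$topology, b$frame, pars)
  expect_equal(tr$coords[1, , ], tr$coords[n_frames(tr), , ],
               tolerance = 1e-12)
  g <- pair_geometry(tr, kink_pivot = NA)
  expect_equal(g$dhh[1], 3.1, tolerance = 0.05)
  expect_equal(g$theta1[1], 0, tolerance = 0.5)
})

test_that("identical seeds give bitwise-identical trajectories", {
  b <- build_initial_system(system_spec("IGF1R", "O4"))
  pars <- bd_params(seed = 42, n_steps = 500, save_interval = 100)
  t1 <- simulate_bd(b$topology, b$frame, pars)
  t2 <- simulate_bd(b$topology, b$frame, pars)
  expect_identical(t1$coords, t2$coords)
  t3 <- simulate_bd(b$topology, b$frame,
                    bd_params(seed = 43, n_steps = 500, save_interval = 100))
  expect_false(identical(t1$coords, t3$coords))
})

test_that("the harmonic tilt potential satisfies equipartition", {
  b <- build_initial_system(system_spec("IR", "O2"))
  k_theta <- 0.02
  pars <- bd_params(seed = 5, n_steps = 60000, save_interval = 200,
                    tilt_potential = list(k = k_theta, theta0 = 30),
                    association_well = list(depth = 0, r0 = 1, width = 0.3))
  tr <- simulate_bd(b$topology, b$frame, pars)
  th <- c(tr$metadata$state$theta1[-(1:100)],
          tr$metadata$state$theta2[-(1:100)])
  expect_lt(abs(stats::var(th) / (kBT(300) / k_theta) - 1), 0.2)
  expect_lt(abs(mean(th) - 30), 2)
})

test_that("sampled tilt matches the Boltzmann density (chi-squared)", {
  b <- build_initial_system(system_spec("IR", "O2"))
  k_theta <- 0.02
  pars <- bd_params(seed = 8, dt = 50, n_steps = 50000, save_interval = 500,
                    tilt_potential = list(k = k_theta, theta0 = 30),
                    association_well = list(depth = 0, r0 = 1, width = 0.3))
  tr <- simulate_bd(b$topology, b$frame, pars)
  # sample both helices at wide spacing for near-independence
  th <- c(tr$metadata$state$theta1[seq(100, 1000, 2)],
          tr$metadata$state$theta2[seq(101, 1000, 2)])
  sd_exp <- sqrt(kBT(300) / k_theta)
  brk <- c(-Inf, seq(30 - 2 * sd_exp, 30 + 2 * sd_exp, length.out = 9), Inf)
  obs <- table(cut(th, brk))
  pr <- diff(stats::pnorm(brk, 30, sd_exp))
  expect_gt(stats::chisq.test(obs, p = pr)$p.value, 0.01)
})

test_that("an association well captures and holds the dimer", {
  b <- build_initial_system(system_spec("IR", "O2"))   # start at 3.5 nm
  pars <- bd_params(seed = 11, n_steps = 20000, save_interval = 100,
                    association_well = list(depth = 5, r0 = 1.0,
                                            width = 0.3))
  tr <- simulate_bd(b$topology, b$frame, pars)
  g <- pair_geometry(tr, kink_pivot = NA)
  st <- detect_dimerization(g$dhh, times = g$time)
  expect_false(is.na(st$first_passage_frame))
  nf <- nrow(g)
  final_half <- g$dhh[(nf %/% 2 + 1):nf]
  expect_gt(mean(final_half <= 1.3), 0.9)
})

test_that("kink dynamics hold the pivot bend at its target", {
  b <- build_initial_system(system_spec("IR", "O5"))
  pars <- bd_params(seed = 3, n_steps = 5000, save_interval = 100,
                    kink = list(pivot = 960, k_bend = 0.05, bend0 = 30),
                    bead_noise = list(core = 0.01, termini = 0.01))
  tr <- simulate_bd(b$topology, b$frame, pars)
  g <- pair_geometry(tr)   # preset pivot for IR is 960
  expect_equal(mean(g$kink1[-(1:10)]), 30, tolerance = 4)
})

test_that("the fixture manifest is deterministic in the intended way", {
  d1 <- file.path(tempdir(), "fix1")
  d2 <- file.path(tempdir(), "fix2")
  d3 <- file.path(tempdir(), "fix3")
  m1 <- make_test_suite_fixtures(d1, seed = 1, n_steps = 1500)
  m2 <- make_test_suite_fixtures(d2, seed = 1, n_steps = 1500)
  m3 <- make_test_suite_fixtures(d3, seed = 2, n_steps = 1500)
  expect_length(m1$files, 13)   # 10 structures + 3 trajectories
  expect_identical(m1$checksums, m2$checksums)
  gro <- grep("\\.gro$", m1$files, value = TRUE)
  trj <- grep("\\.trj", m1$files, value = TRUE)
  expect_identical(m1$checksums[gro], m3$checksums[gro])
  expect_false(any(unlist(m1$checksums[trj]) == unlist(m3$checksums[trj])))
  unlink(c(d1, d2, d3), recursive = TRUE)
})
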