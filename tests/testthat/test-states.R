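test_that("dimer detection applies the inclusive 1.3 nm criterion", {
  st <- detect_dimerization(c(2.0, 1.5, 1.2, 1.1))
  expect_equal(st$dimerized, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(st$first_passage_frame, 3L)   # first frame at/below cutoff
  st2 <- detect_dimerization(rep(5, 10))
  expect_true(all(!st2$dimerized))
  expect_true(is.na(st2$first_passage_frame))
  # boundary is inclusive
  st3 <- detect_dimerization(rep(1.3, 4))
  expect_true(all(st3$dimerized))
  expect_error(detect_dimerization(c(1, NA, 2)), "frame 2")
  expect_error(detect_dimerization(numeric(0)), "empty")
})

test_that("dwell segments partition the frames; detection is monotone in cutoff", {
  set.seed(8)
  for (k in 1:20) {
    d <- runif(50, 0.5, 3)
    st <- detect_dimerization(d)
    segs <- st$dwell_segments
    expect_equal(segs$start[1], 1L)
    expect_equal(segs$end[nrow(segs)], 50L)
    if (nrow(segs) > 1)
      expect_true(all(segs$start[-1] == utils::head(segs$end, -1) + 1))
    lo <- detect_dimerization(d, cutoff = 1.0)
    hi <- detect_dimerization(d, cutoff = 1.8)
    expect_true(all(hi$dimerized[lo$dimerized]))  # raising never unsets
    # idempotence: same input, same output
    expect_identical(detect_dimerization(d)$dimerized, st$dimerized)
  }
  # minimum-dwell filter suppresses a 1-frame flicker
  d <- c(2, 2, 1.2, 2, 2)
  expect_equal(sum(detect_dimerization(d, min_dwell = 2)$dimerized), 0)
  expect_equal(sum(detect_dimerization(d)$dimerized), 1)
})

test_that("Shrake-Rupley matches closed-form sphere and two-sphere areas", {
  top1 <- bead_topology(1, "BB", 1, bead_radius = 0.23)
  fr1 <- md_frame(0, matrix(c(5, 5, 5), 1), c(10, 10, 10))
  R <- 0.23 + 0.185
  s1 <- shrake_rupley_sasa(fr1, top1, probe = 0.185, n_points = 960)
  expect_equal(s1, 4 * pi * R^2, tolerance = 0.01)
  # no occlusion beyond 2(r + probe)
  top2 <- bead_topology(1:2, "BB", 1:2, bead_radius = 0.23)
  fr_far <- md_frame(0, rbind(c(2, 5, 5), c(7, 5, 5)), c(20, 20, 20))
  expect_equal(shrake_rupley_sasa(fr_far, top2, probe = 0.185),
               2 * 4 * pi * R^2, tolerance = 1e-9)
  # overlapping equal spheres vs the spherical-cap formula
  for (d in c(0.3, 0.5, 0.7)) {
    fr2 <- md_frame(0, rbind(c(5, 5, 5), c(5 + d, 5, 5)), c(20, 20, 20))
    s2 <- shrake_rupley_sasa(fr2, top2, probe = 0.185, n_points = 960)
    hcap <- R - d / 2
    exact <- 2 * (4 * pi * R^2 - 2 * pi * R * hcap)
    expect_equal(s2, exact, tolerance = 0.01)
  }
  # quadrature convergence: doubling changes the area by < 0.5%
  s960 <- shrake_rupley_sasa(fr1, top1, n_points = 960)
  s1920 <- shrake_rupley_sasa(fr1, top1, n_points = 1920)
  expect_lt(abs(s1920 / s960 - 1), 0.005)
  expect_equal(shrake_rupley_sasa(fr1, top1, selection = integer(0)), 0)
  expect_error(shrake_rupley_sasa(fr1, top1, n_points = 32), ">= 64")
})

test_that("buried surface area is symmetric, vanishes at separation, grows on contact", {
  top <- pair_topology(10)
  rodA <- rod_coords(10, origin = c(5, 10, 2))
  # far apart: BSA ~ 0
  far <- md_frame(0, rbind(rodA, sweep(rodA, 2, c(8, 0, 0), "+")),
                  c(30, 30, 10))
  b_far <- buried_surface_area(far, top, n_points = 480)
  expect_equal(b_far$bsa, 0, tolerance = 1e-6)
  # exact contact: BSA > 0, symmetric under chain swap
  near <- md_frame(0, rbind(rodA, sweep(rodA, 2, c(0.83, 0, 0), "+")),
                   c(30, 30, 10))
  b_near <- buried_surface_area(near, top, n_points = 480)
  expect_gt(b_near$bsa, 0)
  b_swap <- buried_surface_area(near, top, chainA = "B", chainB = "A",
                                n_points = 480)
  expect_equal(b_near$bsa, b_swap$bsa)
  # two identical parallel rods in contact: occlusion splits evenly, so
  # BSA equals twice one rod's buried area (checked at high resolution)
  b_hi <- buried_surface_area(near, top, n_points = 1920)
  ia <- select_beads(top, chain = "A")
  lost_A <- shrake_rupley_sasa(near, top, ia, n_points = 1920) -
    (b_hi$sasa_AB / 2)
  expect_equal(b_hi$bsa, 2 * lost_A, tolerance = 1e-9)
})

test_that("BSA on generated dimers exceeds BSA on dissociated frames", {
  b <- build_initial_system(system_spec("IR", "O2"))
  tr <- simulate_bd(b$topology, b$frame,
                    bd_params(seed = 11, n_steps = 8000, save_interval = 200))
  g <- pair_geometry(tr, kink_pivot = NA)
  i_dim <- which(g$dhh <= 1.1)[1]
  i_far <- which(g$dhh >= 3.0)[1]
  expect_false(is.na(i_dim) || is.na(i_far))
  bsa <- function(i) buried_surface_area(get_frame(tr, i), tr$topology,
                                         n_points = 480)$bsa
  expect_gt(bsa(i_dim), bsa(i_far))
})

test_that("contact maps average residue-pair distances over dimerized frames", {
  n <- 9
  top <- pair_topology(n)
  rodA <- rod_coords(n, origin = c(10, 10, 2))
  rodB <- sweep(rodA, 2, c(1, 0, 0), "+")
  fr <- rbind(rodA, rodB)
  traj1 <- md_trajectory(top, 50, array(fr, c(1, 2 * n, 3)), c(20, 20, 4))
  cm <- contact_map(traj1, NULL)
  expect_equal(attr(cm, "frame_count"), 1L)
  expect_equal(unname(diag(unclass(cm))), rep(1, n))
  # off-diagonal pairs grow with |i - j| * rise
  expect_equal(unname(cm[1, 3]), sqrt(1 + (2 * 0.15)^2))
  # linearity: mean of two frames equals mean of per-frame maps
  fr2 <- rbind(rodA, sweep(rodA, 2, c(2, 0, 0), "+"))
  coords2 <- aperm(array(c(fr, fr2), c(2 * n, 3, 2)), c(3, 1, 2))
  traj2 <- md_trajectory(top, c(50, 100), coords2, c(20, 20, 4))
  m12 <- contact_map(traj2, NULL)
  m1 <- contact_map(subset_frames(traj2, 1), NULL)
  m2 <- contact_map(subset_frames(traj2, 2), NULL)
  expect_equal(unclass(m12), (unclass(m1) + unclass(m2)) / 2,
               ignore_attr = TRUE)
  # X-crossed rods: map minimum sits at the crossing residue pair
  meet <- rodA[5, ]
  u2 <- c(sin(0.5), 0, cos(0.5))
  rodX <- sweep(outer((seq_len(n) - 5) * 0.15, u2), 2, meet, "+")
  trajX <- md_trajectory(top, 50, aperm(array(c(rbind(rodA, rodX)),
                                              c(2 * n, 3, 1)), c(3, 1, 2)),
                         c(20, 20, 4))
  cmX <- contact_map(trajX, NULL)
  kmin <- which(unclass(cmX) == min(cmX), arr.ind = TRUE)[1, ]
  expect_equal(unname(kmin), c(5, 5))
  st_none <- detect_dimerization(rep(5, 1))
  expect_error(contact_map(trajX, st_none), "threshold")
})

test_that("packing classifier reproduces the exemplar configurations", {
  g <- data.frame(time = c(1, 2, 3), dhh = c(1.15, 0.9, 1.2),
                  omega = c(25, 2, 8), kink1 = c(10, 5, 25),
                  kink2 = c(8, 4, 20),
                  crossing_residue = c(960L, NA, NA))
  expect_equal(classify_packing(g), c("X", "parallel", "V"))
  # non-dimerized frames are rejected
  g$dhh[1] <- 2.5
  expect_error(classify_packing(g), "dimerized")
  # thresholds partition the exemplar ranges without overlap
  th <- packing_thresholds()
  expect_lt(th$omega_p, th$omega_x)
  expect_lt(th$dhh_parallel_max, th$dhh_dimer_max)
})

test_that("state tables label dissociated frames 'none'", {
  g <- data.frame(time = c(50, 100, 150), dhh = c(3, 1.2, 0.9),
                  omega = c(20, 25, 1), kink1 = c(5, 5, 5),
                  kink2 = c(5, 5, 5), crossing_residue = c(NA, 960L, NA))
  stt <- state_table(g)
  expect_equal(stt$table$mode, c("none", "X", "parallel"))
  expect_equal(stt$state$first_passage_frame, 2L)
})
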