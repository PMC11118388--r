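box <- c(20, 20, 4)

test_that("fit_axis recovers exact and noisy helix axes", {
  top <- rod_topology(23)
  # exact line along z
  fr <- md_frame(0, rod_coords(23), box)
  ax <- fit_axis(fr, top, "A", c(1, 23))
  expect_equal(ax$direction, c(0, 0, 1), tolerance = 1e-9)
  # rotation equivariance: 30 degrees about y
  R <- rot3(c(0, 1, 0), 30)
  fr2 <- md_frame(0, rod_coords(23) %*% t(R), box)
  ax2 <- fit_axis(fr2, top, "A", c(1, 23))
  expect_equal(tilt_angle(ax2), 30, tolerance = 1e-6)
  # noisy ideal helix: axis within 2 degrees of the generating axis
  set.seed(99)
  worst <- 0
  for (k in 1:100) {
    u <- c(sin(0.3), 0, cos(0.3))
    xyz <- tmdimer:::ideal_helix(23, u, 0.15, 0.23) +
      matrix(rnorm(69, 0, 0.02), 23, 3)
    axn <- fit_axis(md_frame(0, xyz, box), top, "A", c(1, 23))
    ang <- acos(min(1, abs(sum(axn$direction * u)))) * 180 / pi
    worst <- max(worst, ang)
  }
  expect_lt(worst, 2)
})

test_that("fit_axis orientation fix is stable under bead-order reversal", {
  top <- rod_topology(11)
  up <- rod_coords(11)
  down <- up[11:1, ]   # same line, beads listed N-to-C the other way
  a1 <- fit_axis(md_frame(0, up, box), top, "A", c(1, 11))
  a2 <- fit_axis(md_frame(0, down, box), top, "A", c(1, 11))
  expect_equal(a1$direction, a2$direction)
  expect_error(fit_axis(md_frame(0, up, box), top, "A", c(1, 2)),
               "at least 3")
})

test_that("tilt and crossing angles hit the constructed identities", {
  expect_equal(tilt_angle(c(0, 0, 1)), 0)
  expect_equal(tilt_angle(c(1, 0, 1) / sqrt(2)), 45)
  expect_equal(tilt_angle(c(1, 0, 0)), 90)
  expect_equal(crossing_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  u <- c(sin(pi / 4), 0, cos(pi / 4))
  expect_equal(crossing_angle(c(0, 0, 1), u), 45)
  expect_equal(crossing_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_error(tilt_angle(c(0, 0, 1), c(0, 0, 2)), "unit")
})

test_that("tilt/crossing are invariant under in-plane rotation and translation", {
  set.seed(4)
  top <- pair_topology(15)
  for (k in 1:20) {
    u1 <- rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- rnorm(3); u2 <- u2 / sqrt(sum(u2^2))
    c1 <- rod_coords(15, u1, origin = c(8, 10, 2))
    c2 <- rod_coords(15, u2, origin = c(12, 10, 2))
    fr <- md_frame(0, rbind(c1, c2), box)
    Rz <- rot3(c(0, 0, 1), runif(1, 0, 360))
    shift <- c(runif(2, -2, 2), 0)
    fr2 <- md_frame(0, sweep(rbind(c1, c2) %*% t(Rz), 2, shift, "+"), box)
    a1 <- fit_axis(fr, top, "A", c(1, 15)); b1 <- fit_axis(fr2, top, "A", c(1, 15))
    a2 <- fit_axis(fr, top, "B", c(1, 15)); b2 <- fit_axis(fr2, top, "B", c(1, 15))
    expect_equal(tilt_angle(b1), tilt_angle(a1), tolerance = 1e-8)
    expect_equal(crossing_angle(b1, b2), crossing_angle(a1, a2),
                 tolerance = 1e-8)
    expect_equal(crossing_angle(a1, a2), crossing_angle(a2, a1))
    expect_true(tilt_angle(a1) >= 0 && tilt_angle(a1) <= 90)
    expect_true(crossing_angle(a1, a2) >= 0 && crossing_angle(a1, a2) <= 90)
  }
})

test_that("interhelical distance honours geometry and the periodic plane", {
  top <- pair_topology(5)
  c1 <- rod_coords(5, origin = c(5, 5, 2))
  fr0 <- md_frame(0, rbind(c1, c1), box)
  expect_equal(interhelical_distance(fr0, top, c(1, 5), c(1, 5)), 0)
  # 3-4-5 triangle
  c2 <- sweep(c1, 2, c(0.3, 0.4, 0), "+")
  fr <- md_frame(0, rbind(c1, c2), box)
  expect_equal(interhelical_distance(fr, top, c(1, 5), c(1, 5)), 0.5)
  # minimum image in x: 18 nm apart in a 20 nm box is really 2 nm
  c3 <- sweep(c1, 2, c(18, 0, 0), "+")
  frp <- md_frame(0, rbind(c1, c3), box)
  expect_equal(interhelical_distance(frp, top, c(1, 5), c(1, 5)), 2)
  expect_error(interhelical_distance(fr, top, c(90, 95), c(1, 5)), "empty")
})

test_that("kink angle reproduces constructed bends", {
  n <- 21; pivot <- 11
  top <- rod_topology(n)
  straight <- rod_coords(n)
  expect_equal(kink_angle(md_frame(0, straight, box), top, "A", pivot, 5), 0,
               tolerance = 1e-6)
  # bend the C-terminal half by 30 degrees at the pivot bead
  bend30 <- straight
  R <- rot3(c(0, 1, 0), 30)
  piv <- straight[pivot, ]
  lower <- (pivot + 1):n
  bend30[lower, ] <- sweep(sweep(straight[lower, ], 2, piv) %*% t(R), 2,
                           piv, "+")
  expect_equal(kink_angle(md_frame(0, bend30, box), top, "A", pivot, 5), 30,
               tolerance = 1)
  expect_error(kink_angle(md_frame(0, straight, box), top, "A", 2, 5),
               "outside")
  # noisy bent helix: the estimator's error budget follows from line-fit
  # error propagation (direction sd ~ sigma/sqrt(sum (t - tbar)^2) per
  # transverse dimension, two sub-axes); at halfspan 7 that is ~1.4 deg
  # rms, so the mean absolute error over 100 seeds stays under 3 deg
  set.seed(123)
  errs <- replicate(100, {
    noisy <- bend30 + matrix(rnorm(n * 3, 0, 0.02), n, 3)
    kink_angle(md_frame(0, noisy, box), top, "A", pivot, 7) - 30
  })
  expect_lt(mean(abs(errs)), 3)
  expect_lt(max(abs(errs)), 8)
})

test_that("crossing point localizes the construction and matches a grid oracle", {
  n <- 41
  top <- pair_topology(n, first_res = 940)
  # two lines crossing exactly at the bead of residue 960 (index 21)
  c1 <- rod_coords(n, c(0, 0, 1), origin = c(10, 10, 2))
  meet <- c1[21, ]
  u2 <- c(sin(0.6), 0, cos(0.6))
  c2 <- sweep(outer((seq_len(n) - 21) * 0.15, -u2), 2, meet, "+")
  fr <- md_frame(0, rbind(c1, c2), box)
  a1 <- fit_axis(fr, top, "A", c(940, 980))
  a2 <- fit_axis(fr, top, "B", c(940, 980))
  cp <- crossing_point(a1, a2, fr, top)
  expect_equal(cp$residue, 960)
  expect_lt(cp$min_approach, 1e-6)
  # parallel axes 1 nm apart
  c3 <- sweep(c1, 2, c(1, 0, 0), "+")
  frp <- md_frame(0, rbind(c1, c3), box)
  p1 <- fit_axis(frp, top, "A", c(940, 980))
  p2 <- fit_axis(frp, top, "B", c(940, 980))
  cpp <- crossing_point(p1, p2, frp, top)
  expect_true(is.na(cpp$residue))
  expect_equal(cpp$min_approach, 1)
  # random skew lines vs dense two-parameter minimization
  set.seed(21)
  for (k in 1:10) {
    ax1 <- structure(list(centroid = runif(3, 4, 16),
                          direction = { v <- rnorm(3); v / sqrt(sum(v^2)) },
                          span_residues = c(940, 980)), class = "helix_axis")
    ax2 <- structure(list(centroid = runif(3, 4, 16),
                          direction = { v <- rnorm(3); v / sqrt(sum(v^2)) },
                          span_residues = c(940, 980)), class = "helix_axis")
    got <- crossing_point(ax1, ax2, fr, top, bound = Inf)$min_approach
    line_dist <- function(t1, t2) {
      dx <- ax1$centroid[1] + t1 * ax1$direction[1] -
        (ax2$centroid[1] + t2 * ax2$direction[1])
      dy <- ax1$centroid[2] + t1 * ax1$direction[2] -
        (ax2$centroid[2] + t2 * ax2$direction[2])
      dz <- ax1$centroid[3] + t1 * ax1$direction[3] -
        (ax2$centroid[3] + t2 * ax2$direction[3])
      sqrt(dx^2 + dy^2 + dz^2)
    }
    # two-stage dense grid over both line parameters
    tt <- seq(-40, 40, length.out = 400)
    d1 <- outer(tt, tt, line_dist)
    kk <- which(d1 == min(d1), arr.ind = TRUE)[1, ]
    step <- tt[2] - tt[1]
    t1f <- seq(tt[kk[1]] - step, tt[kk[1]] + step, length.out = 400)
    t2f <- seq(tt[kk[2]] - step, tt[kk[2]] + step, length.out = 400)
    dmin <- min(outer(t1f, t2f, line_dist))
    expect_lte(got, dmin + 1e-6)
    expect_lt(abs(got - dmin), 1e-6)
  }
})

test_that("Kabsch RMSD is zero on rigid copies and matches the quaternion oracle", {
  set.seed(5)
  P <- matrix(rnorm(45), 15, 3)
  expect_equal(kabsch_rmsd(P, P), 0)
  R <- rot3(rnorm(3), 77)
  Q <- sweep(P %*% t(R), 2, c(1, -2, 3), "+")
  expect_lt(kabsch_rmsd(P, Q), 1e-9)
  # single displaced bead: RMSD <= delta/sqrt(N)
  Q2 <- P; Q2[4, ] <- Q2[4, ] + c(0.3, 0, 0)
  expect_lte(kabsch_rmsd(P, Q2), 0.3 / sqrt(15) + 1e-12)
  expect_error(kabsch_rmsd(P, Q2[1:10, ]), "differ in size")
  # oracle agreement on random pairs
  for (k in 1:10) {
    A <- matrix(rnorm(30), 10, 3)
    B <- A + matrix(rnorm(30, 0, 0.3), 10, 3)
    expect_equal(kabsch_rmsd(A, B), quat_rmsd_oracle(A, B),
                 tolerance = 1e-6)
  }
})

test_that("Kabsch RMSD is a pseudometric and agrees with bio3d superposition", {
  set.seed(31)
  for (k in 1:10) {
    A <- matrix(rnorm(36), 12, 3)
    B <- matrix(rnorm(36), 12, 3)
    C <- matrix(rnorm(36), 12, 3)
    ab <- kabsch_rmsd(A, B); ba <- kabsch_rmsd(B, A)
    expect_equal(ab, ba, tolerance = 1e-9)
    expect_lte(ab, kabsch_rmsd(A, C) + kabsch_rmsd(C, B) + 1e-9)
  }
  A <- matrix(rnorm(36), 12, 3)
  B <- A + matrix(rnorm(36, 0, 0.2), 12, 3)
  ref <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
  expect_equal(kabsch_rmsd(A, B), ref, tolerance = 1e-3)
})

test_that("pair_geometry tables are internally consistent on generated dimers", {
  tr <- simulate_bd(two_helix_topology("IR"),
                    build_initial_system(system_spec("IR", "O5"))$frame,
                    bd_params(seed = 2, n_steps = 1000, save_interval = 100))
  g <- pair_geometry(tr)
  expect_s3_class(g, "pair_geometry")
  expect_equal(nrow(g), n_frames(tr))
  expect_true(all(g$dhh >= 0))
  expect_true(all(g$theta1 >= 0 & g$theta1 <= 90))
  expect_true(all(g$omega >= 0 & g$omega <= 90))
  expect_true(all(g$kink1 >= 0 & g$kink1 <= 180))
  # crossing residue only reported within the proximity bound
  expect_true(all(is.na(g$crossing_residue) | g$min_approach <= 1.5))
})
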