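#' Specification of a two-helix starting system
#'
#' Encodes the standard starting-orientation table: five initial
#' orientations (O1-O5) per receptor, each defined by the initial
#' inter-helical distance, tilt and crossing angle, with three 10-us
#' production replicates configured per system. Recorded system sizes
#' (atoms) are metadata only; solvent packing is not modelled.
#'
#' @param receptor "IR" or "IGF1R".
#' @param orientation one of "O1".."O5".
#' @return a \code{system_spec} list with fields \code{receptor},
#'   \code{orientation}, \code{initial_dhh} (nm), \code{initial_theta},
#'   \code{initial_omega} (deg), \code{closest_residue_gap} (nm),
#'   \code{box} (nm), \code{replicate_count},
#'   \code{production_length_us} (per replicate), \code{total_us},
#'   \code{system_size_atoms}.
#' @export
system_spec <- function(receptor = c("IR", "IGF1R"),
                        orientation = c("O1", "O2", "O3", "O4", "O5")) {
  receptor <- match.arg(receptor)
  orientation <- match.arg(orientation)
  p <- tmd_preset(receptor)
  o <- p$orientations[[orientation]]
  k <- as.integer(sub("O", "", orientation))
  structure(list(receptor = receptor, orientation = orientation,
                 initial_dhh = o$dhh, initial_theta = o$theta,
                 initial_omega = o$omega,
                 closest_residue_gap = 2.5,
                 box = c(20, 20, 4),
                 replicate_count = 3L,
                 production_length_us = 10,
                 total_us = p$production_us,
                 system_size_atoms = p$system_size[[k]]),
            class = "system_spec")
}

#' All ten starting systems (both receptors, five orientations)
#' @return list of \code{system_spec}.
#' @export
all_system_specs <- function() {
  out <- list()
  for (r in c("IR", "IGF1R"))
    for (o in paste0("O", 1:5))
      out[[paste(r, o, sep = "_")]] <- system_spec(r, o)
  out
}

# rotation matrix, Rodrigues form
rotation_about <- function(axis, angle_deg) {
  a <- .deg2rad(angle_deg)
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

sphere2cart <- function(theta_deg, phi_deg) {
  th <- .deg2rad(theta_deg); ph <- .deg2rad(phi_deg)
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

# ideal helix beads: N-terminus (first residue) toward +z along axis u
ideal_helix <- function(n, u, rise = 0.15, helix_radius = 0.23,
                        twist_deg = 100, phase_deg = 0) {
  u <- u / sqrt(sum(u^2))
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  j <- seq_len(n)
  t_ax <- ((n + 1) / 2 - j) * rise           # residue 1 highest along +u
  ang <- .deg2rad((j - 1) * twist_deg + phase_deg)
  outer(t_ax, u) + helix_radius * (outer(cos(ang), e1) + outer(sin(ang), e2))
}

#' Build a two-helix starting structure
#'
#' Places two ideal 49-residue helical bead rods (one backbone bead per
#' residue, 0.15 nm rise, 100 deg/residue twist) in a 20 x 20 x 4 nm
#' membrane slab so that the analysis metrics measured on the built frame
#' (d_HH over the receptor's distance span, tilt over its tilt span,
#' crossing angle) reproduce the requested starting orientation.
#' N-termini point toward +z (the extracellular side). Because an ideal
#' helix with a non-integer number of turns biases a principal-axis fit
#' slightly, each helix is refined by a few corrective rotations until
#' its fitted axis matches the target direction.
#'
#' @param spec a \code{system_spec} (or receptor/orientation to build one).
#' @param receptor,orientation used if \code{spec} is NULL.
#' @param helix_radius ideal-helix radius in nm (default 0.23).
#' @param bead_radius bead radius in nm (default 0.23).
#' @param rise helical rise per residue in nm (default 0.15).
#' @return list with \code{topology}, \code{frame}, \code{spec} and
#'   \code{closest_residue_gap} (nm, measured between closest beads of
#'   the two chains).
#' @export
build_initial_system <- function(spec = NULL, receptor = "IR",
                                 orientation = "O1", helix_radius = 0.23,
                                 bead_radius = 0.23, rise = 0.15) {
  if (is.null(spec)) spec <- system_spec(receptor, orientation)
  if (spec$initial_dhh < 2 * bead_radius)
    stop("requested d_HH (", spec$initial_dhh,
         " nm) is below hard-core contact of the beads")
  p <- tmd_preset(spec$receptor)
  top <- two_helix_topology(spec$receptor, bead_radius = bead_radius)
  n <- sum(top$chain_id == "A")
  box <- spec$box
  theta <- spec$initial_theta
  omega <- spec$initial_omega
  if (theta > 1e-9) {
    ct <- cos(.deg2rad(theta))^2; st <- sin(.deg2rad(theta))^2
    carg <- (cos(.deg2rad(omega)) - ct) / st
    if (carg < -1 - 1e-9 || carg > 1 + 1e-9)
      stop("crossing angle ", omega, " deg unreachable at tilt ", theta)
    dphi <- .rad2deg(acos(max(-1, min(1, carg))))
  } else {
    if (omega > 1e-9)
      stop("crossing angle ", omega, " deg unreachable at tilt 0")
    dphi <- 0
  }
  phis <- c(90 + dphi / 2, 90 - dphi / 2)
  tilt_span <- as_span(p$tilt_span)
  dhh_span <- as_span(p$dhh_span)
  res <- seq(p$residues$first, p$residues$last)
  build_chain <- function(phi, chain) {
    u_target <- sphere2cart(theta, phi)
    xyz <- ideal_helix(n, u_target, rise, helix_radius)
    idx_chain <- select_beads(top, chain = chain)
    # corrective rotations: align the fitted span axis to the target
    for (it in 1:6) {
      fr <- fake_frame(top, xyz, idx_chain, box)
      ax <- fit_axis(fr, top, chain, tilt_span, orient = "nc")
      u_fit <- -ax$direction                 # N->C runs against +z here
      err <- .rad2deg(acos(max(-1, min(1, sum(u_fit * u_target)))))
      if (err < 0.02) break
      rotax <- c(u_fit[2] * u_target[3] - u_fit[3] * u_target[2],
                 u_fit[3] * u_target[1] - u_fit[1] * u_target[3],
                 u_fit[1] * u_target[2] - u_fit[2] * u_target[1])
      if (sqrt(sum(rotax^2)) < 1e-12) break
      R <- rotation_about(rotax, err)
      ctr <- colMeans(xyz)
      xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, "+")
    }
    xyz
  }
  xyz1 <- build_chain(phis[1], "A")
  xyz2 <- build_chain(phis[2], "B")
  span_centroid <- function(xyz, span) {
    keep <- res >= span[1] & res <= span[2]
    colMeans(xyz[keep, , drop = FALSE])
  }
  c1_target <- c(box[1] / 2 - spec$initial_dhh / 2, box[2] / 2, box[3] / 2)
  c2_target <- c(box[1] / 2 + spec$initial_dhh / 2, box[2] / 2, box[3] / 2)
  xyz1 <- sweep(xyz1, 2, c1_target - span_centroid(xyz1, dhh_span), "+")
  xyz2 <- sweep(xyz2, 2, c2_target - span_centroid(xyz2, dhh_span), "+")
  coords <- rbind(xyz1, xyz2)
  frame <- md_frame(0, coords, box)
  dmat <- as.matrix(stats::dist(rbind(xyz1, xyz2)))
  gap <- min(dmat[seq_len(n), n + seq_len(n)])
  list(topology = top, frame = frame, spec = spec,
       closest_residue_gap = gap)
}

# frame where only one chain's rows are meaningful (builder internal)
fake_frame <- function(top, xyz_chain, idx_chain, box) {
  coords <- matrix(0, nrow(top), 3)
  coords[idx_chain, ] <- xyz_chain
  md_frame(0, coords, box)
}

# ---- membrane composition bookkeeping ------------------------------------

#' Plasma-membrane composition of the simulated system
#'
#' Default counts describe the asymmetric plasma-membrane mimic used for
#' the two-helix systems: 1600 lipids (800 per leaflet), outer leaflet
#' 360 CHOL / 248 POPC / 136 POSM / 56 POPE, inner leaflet 328 CHOL /
#' 168 POPE / 120 POPC / 80 POPS / 72 POSM / 32 POPI, 15312 CG waters and
#' 150 mM salt (314 Na+, 202 Cl-). POPS and POPI carry one negative
#' charge each.
#'
#' @param outer,inner named integer vectors of per-leaflet lipid counts.
#' @param water_count CG water count.
#' @param na_count,cl_count ion counts.
#' @param salt_mM nominal salt concentration.
#' @return a \code{membrane_composition} list.
#' @export
membrane_composition <- function(
    outer = c(CHOL = 360, POPC = 248, POSM = 136, POPE = 56),
    inner = c(CHOL = 328, POPE = 168, POPC = 120, POPS = 80, POSM = 72,
              POPI = 32),
    water_count = 15312, na_count = 314, cl_count = 202, salt_mM = 150) {
  structure(list(outer = outer, inner = inner, water_count = water_count,
                 na_count = na_count, cl_count = cl_count,
                 salt_mM = salt_mM),
            class = "membrane_composition")
}

# per-lipid formal charges; everything else neutral
.lipid_charge <- c(POPS = -1, POPI = -1)

#' Composition and electroneutrality report
#'
#' Totals per leaflet and overall, the net lipid charge (POPS and POPI
#' carry -1 each) and the ion counts required for electroneutrality
#' (Na+ = Cl- + |net negative lipid charge|).
#'
#' @param comp a \code{membrane_composition}.
#' @param strict if TRUE (default), leaflets must hold 800 lipids each.
#' @return list with \code{outer_total}, \code{inner_total},
#'   \code{lipid_total}, \code{net_lipid_charge}, \code{na_required},
#'   \code{na_count}, \code{cl_count}, \code{electroneutral} (logical)
#'   and \code{water_count}.
#' @export
composition_report <- function(comp = membrane_composition(), strict = TRUE) {
  ot <- sum(comp$outer); it <- sum(comp$inner)
  if (strict && (ot != 800 || it != 800))
    stop("composition error: leaflets hold ", ot, " and ", it,
         " lipids (expected 800 each)")
  all_lip <- c(comp$outer, comp$inner)
  chg <- sum(all_lip * .lipid_charge[names(all_lip)], na.rm = TRUE)
  na_req <- comp$cl_count + abs(chg)
  list(outer_total = ot, inner_total = it, lipid_total = ot + it,
       net_lipid_charge = chg, na_required = na_req,
       na_count = comp$na_count, cl_count = comp$cl_count,
       electroneutral = (comp$na_count - comp$cl_count + chg) == 0,
       water_count = comp$water_count)
}

# ---- Brownian-dynamics two-helix generator -------------------------------

#' Parameters of the Brownian-dynamics two-helix generator
#'
#' The generator is a statistical test harness with imposed potentials,
#' not a physical model of CG force-field dynamics: each helix's
#' in-plane centre of mass performs overdamped 2-D Brownian motion under
#' a Gaussian association well, tilt (and, when dimerized, crossing)
#' angles follow exact Ornstein-Uhlenbeck dynamics on harmonic
#' potentials, and rigid-rod bead positions are regenerated from
#' (COM, axis, kink state) each saved frame with per-bead noise that is
#' larger outside the membrane-embedded span (floppy termini).
#'
#' @param seed RNG seed (determinism contract: identical seed + params
#'   give identical trajectories).
#' @param dt time step in ps.
#' @param n_steps number of BD steps.
#' @param temperature K.
#' @param lateral_diffusion per-helix in-plane diffusion, nm^2/ps.
#' @param rotational_diffusion angular diffusion, rad^2/ps.
#' @param tilt_potential list(k, theta0): harmonic tilt potential,
#'   k in kcal/mol/deg^2, theta0 in degrees (applied to both helices).
#' @param omega_potential list(k, omega0): harmonic crossing-angle
#'   potential, active only while dimerized.
#' @param association_well list(depth, r0, width): Gaussian well in the
#'   COM separation, kcal/mol and nm.
#' @param kink NULL or list(pivot, k_bend, bend0): OU dynamics of the
#'   kink angle at the pivot residue (deg).
#' @param save_interval ps between saved frames (default 50).
#' @param bead_noise list(core, termini): per-coordinate Gaussian bead
#'   jitter in nm inside/outside the membrane span.
#' @param rigid_span residue range treated as membrane-embedded (default:
#'   the receptor preset's membrane span when inferable, else the middle
#'   55 percent of the chain).
#' @param dimer_cutoff COM separation (nm) below which the pair counts as
#'   dimerized for the omega coupling (default 1.3).
#' @param core_radius,core_k harmonic core repulsion (nm, kcal/mol/nm^2).
#' @param rise,helix_radius rod geometry (nm).
#' @return a \code{bd_params} list.
#' @export
bd_params <- function(seed = 1, dt = 10, n_steps = 10000, temperature = 300,
                      lateral_diffusion = 1e-4, rotational_diffusion = 1e-4,
                      tilt_potential = list(k = 0.02, theta0 = 30),
                      omega_potential = list(k = 0.05, omega0 = 25),
                      association_well = list(depth = 5, r0 = 1.0,
                                              width = 0.3),
                      kink = NULL, save_interval = 50,
                      bead_noise = list(core = 0.02, termini = 0.08),
                      rigid_span = NULL, dimer_cutoff = 1.3,
                      core_radius = 0.5, core_k = 100,
                      rise = 0.15, helix_radius = 0) {
  stopifnot(dt > 0, n_steps >= 1, association_well$depth >= 0,
            tilt_potential$k >= 0, omega_potential$k >= 0)
  structure(as.list(environment()), class = "bd_params")
}

# initial BD state measured from a start frame
bd_init_state <- function(topology, start, rigid_span) {
  axA <- fit_axis(start, topology, "A", rigid_span)
  axB <- fit_axis(start, topology, "B", rigid_span)
  angles <- function(u) {
    th <- .rad2deg(acos(max(-1, min(1, u[3]))))
    ph <- .rad2deg(atan2(u[2], u[1]))
    c(th, ph)
  }
  a1 <- angles(axA$direction); a2 <- angles(axB$direction)
  list(com1 = axA$centroid, com2 = axB$centroid,
       theta = c(a1[1], a2[1]), phi = c(a1[2], a2[2]),
       omega = crossing_angle(axA, axB), bend = c(0, 0))
}

# exact OU update toward mu with stationary sd s and relaxation a
ou_step <- function(x, mu, a, s, z) mu + (x - mu) * a + s * sqrt(1 - a^2) * z

reflect_angle <- function(x, lo = 0, hi = 180) {
  x <- abs(x - lo) + lo
  over <- x > hi
  x[over] <- 2 * hi - x[over]
  x
}

#' Simulate a two-helix Brownian-dynamics trajectory
#'
#' Overdamped Langevin dynamics of the reduced coordinates described in
#' \code{\link{bd_params}}, starting from a built frame. Deterministic
#' under a fixed seed; frames are emitted every \code{save_interval} ps.
#'
#' @param topology a \code{bead_topology} (two chains).
#' @param start an \code{md_frame} (e.g. from
#'   \code{\link{build_initial_system}}).
#' @param params a \code{bd_params}.
#' @return an \code{md_trajectory} with generator provenance in
#'   \code{metadata}.
#' @export
simulate_bd <- function(topology, start, params = bd_params()) {
  seg <- bd_core(topology, start, params, state = NULL)
  md_trajectory(topology, seg$times, seg$coords, start$box,
                metadata = list(generator = "bd", seed = params$seed,
                                params = params, state = seg$state_series))
}

#' Simulate a trajectory whose parameters switch on a schedule
#'
#' Runs \code{\link{simulate_bd}} segments back to back, carrying the
#' dynamic state across segment boundaries, with per-segment parameter
#' overrides (e.g. to alternate two imposed packing modes with a known
#' dwell-time ratio).
#'
#' @param topology a \code{bead_topology}.
#' @param start an \code{md_frame}.
#' @param base_params a \code{bd_params} shared by all segments.
#' @param segments list of lists, each with \code{n_steps} and an
#'   optional \code{override} list merged onto \code{base_params}.
#' @return an \code{md_trajectory}; \code{metadata$segment_of_frame}
#'   records which segment produced each frame.
#' @export
simulate_bd_schedule <- function(topology, start, base_params, segments) {
  oldseed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed,
                                        envir = globalenv()))
  set.seed(base_params$seed)
  state <- NULL
  times <- numeric(0); coords <- NULL; segment_of_frame <- integer(0)
  t0 <- 0
  for (s in seq_along(segments)) {
    p <- base_params
    ov <- segments[[s]]$override
    if (!is.null(ov)) p[names(ov)] <- ov
    p$n_steps <- segments[[s]]$n_steps
    p$seed <- NULL                      # RNG stream continues across segments
    seg <- bd_core(topology, start, p, state = state, t_offset = t0,
                   reseed = FALSE)
    state <- seg$final_state
    t0 <- seg$t_end
    times <- c(times, seg$times)
    coords <- if (is.null(coords)) seg$coords else {
      a <- array(0, dim = c(dim(coords)[1] + dim(seg$coords)[1],
                            dim(coords)[2], 3))
      a[seq_len(dim(coords)[1]), , ] <- coords
      a[dim(coords)[1] + seq_len(dim(seg$coords)[1]), , ] <- seg$coords
      a
    }
    segment_of_frame <- c(segment_of_frame, rep(s, length(seg$times)))
  }
  md_trajectory(topology, times, coords, start$box,
                metadata = list(generator = "bd_schedule",
                                seed = base_params$seed,
                                segment_of_frame = segment_of_frame))
}

# core integrator; returns saved state series and regenerated bead coords
bd_core <- function(topology, start, params, state = NULL, t_offset = 0,
                    reseed = TRUE) {
  p <- params
  if (reseed) {
    oldseed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed,
                                          envir = globalenv()))
    set.seed(p$seed)
  }
  top <- topology
  box <- start$box
  thermal <- p$temperature > 0          # T = 0 freezes all stochastic terms
  kT <- kBT(max(p$temperature, 0))
  Ddeg <- p$rotational_diffusion * (180 / pi)^2    # deg^2/ps
  rigid_span <- p$rigid_span
  if (is.null(rigid_span)) {
    pr <- tryCatch(infer_preset(top), error = function(e) NULL)
    rigid_span <- if (!is.null(pr)) as_span(pr$membrane_span) else {
      rng <- range(top$residue_number)
      round(rng[1] + c(0.225, 0.775) * diff(rng))
    }
  } else rigid_span <- as_span(rigid_span)
  if (is.null(state)) state <- bd_init_state(top, start, rigid_span)
  # OU coefficients (exact discretization; variance k_B T / k at any dt)
  ou_coef <- function(k) {
    if (k <= 0) return(list(a = 1, s = 0, free = TRUE))
    tau <- kT / (Ddeg * k)
    list(a = exp(-p$dt / tau), s = sqrt(kT / k), free = FALSE)
  }
  oc_t <- ou_coef(p$tilt_potential$k)
  oc_o <- ou_coef(p$omega_potential$k)
  oc_b <- if (!is.null(p$kink)) ou_coef(p$kink$k_bend) else NULL
  sig_rot <- if (thermal) sqrt(2 * Ddeg * p$dt) else 0
  sig_lat <- if (thermal) sqrt(2 * p$lateral_diffusion * p$dt) else 0
  mob <- if (thermal) p$lateral_diffusion / kT else 0  # nm^2/(ps kcal/mol)
  if (!thermal) p$bead_noise <- list(core = 0, termini = 0)
  save_every <- max(1L, round(p$save_interval / p$dt))
  n_save <- floor(p$n_steps / save_every)
  if (n_save < 1) stop("n_steps too small for one saved frame")
  Z <- matrix(stats::rnorm(p$n_steps * 11), ncol = 11)
  S <- matrix(0, n_save, 11)  # com1 xy, com2 xy, th1 th2, ph1 ph2, om, b1 b2
  com1 <- state$com1[1:2]; com2 <- state$com2[1:2]
  z_mid <- c(state$com1[3], state$com2[3])
  th <- state$theta; ph <- state$phi
  om <- state$omega; bend <- state$bend
  dphi_sign <- 1
  ks <- 0L
  for (s in seq_len(p$n_steps)) {
    dvec <- min_image_xy(c(com2 - com1, 0), box)[1:2]
    r <- sqrt(sum(dvec^2))
    # association well + core repulsion force on helix 2 along +dvec
    fr <- 0
    if (p$association_well$depth > 0) {
      w <- p$association_well
      fr <- fr - w$depth * (r - w$r0) / w$width^2 *
        exp(-(r - w$r0)^2 / (2 * w$width^2))
    }
    if (r < p$core_radius) fr <- fr + p$core_k * (p$core_radius - r)
    fhat <- if (r > 1e-9) dvec / r else c(1, 0)
    step1 <- -mob * fr * fhat * p$dt + sig_lat * Z[s, 1:2]
    step2 <- mob * fr * fhat * p$dt + sig_lat * Z[s, 3:4]
    if (max(abs(c(step1, step2))) > min(box[1:2]) / 2)
      stop("BD stability error: displacement exceeded half the box; ",
           "reduce dt or the forces")
    com1 <- (com1 + step1) %% box[1:2]
    com2 <- (com2 + step2) %% box[1:2]
    dimerized <- r <= p$dimer_cutoff
    # tilt OU (or free diffusion when k = 0), reflected into [0, 180]
    if (oc_t$free) {
      th <- reflect_angle(th + sig_rot * Z[s, 5:6])
    } else {
      th <- reflect_angle(ou_step(th, p$tilt_potential$theta0, oc_t$a,
                                  oc_t$s, Z[s, 5:6]))
    }
    if (dimerized && !oc_o$free) {
      # an interface locks the attack angle: the pair's mean azimuth
      # tracks the inter-COM direction while the crossing angle follows
      # its own OU dynamics
      om <- reflect_angle(ou_step(om, p$omega_potential$omega0, oc_o$a,
                                  oc_o$s, Z[s, 8]), 0, 90)
      alpha <- .rad2deg(atan2(dvec[2], dvec[1]))
      psi <- (ph[1] + ph[2]) / 2
      dpsi <- ((psi - alpha + 180) %% 360) - 180
      psi <- alpha + dpsi * oc_o$a + oc_o$s * sqrt(1 - oc_o$a^2) * Z[s, 11]
      ca <- (cos(.deg2rad(om)) -
               cos(.deg2rad(th[1])) * cos(.deg2rad(th[2])))
      sa <- sin(.deg2rad(th[1])) * sin(.deg2rad(th[2]))
      dphi <- if (sa > 1e-9) .rad2deg(acos(max(-1, min(1, ca / sa)))) else 0
      ph[1] <- psi - dphi_sign * dphi / 2
      ph[2] <- psi + dphi_sign * dphi / 2
    } else {
      ph[1] <- ph[1] + sig_rot * Z[s, 7]
      ph[2] <- ph[2] + sig_rot * Z[s, 8]
      u1 <- sphere2cart(th[1], ph[1]); u2 <- sphere2cart(th[2], ph[2])
      om <- crossing_angle(u1, u2)
      dd <- ((ph[2] - ph[1] + 180) %% 360) - 180   # wrapped to (-180, 180]
      dphi_sign <- if (dd >= 0) 1 else -1
    }
    if (!is.null(oc_b)) {
      if (oc_b$free) bend <- reflect_angle(bend + sig_rot * Z[s, 9:10],
                                           0, 180)
      else bend <- reflect_angle(ou_step(bend, p$kink$bend0, oc_b$a, oc_b$s,
                                         Z[s, 9:10]), 0, 180)
    }
    if (s %% save_every == 0) {
      ks <- ks + 1L
      S[ks, ] <- c(com1, com2, th, ph, om, bend)
    }
  }
  coords <- regenerate_beads(top, S, z_mid, p, rigid_span, box)
  times <- t_offset + seq_len(n_save) * save_every * p$dt
  list(times = times, coords = coords,
       state_series = stats::setNames(as.data.frame(S),
         c("x1", "y1", "x2", "y2", "theta1", "theta2", "phi1", "phi2",
           "omega", "bend1", "bend2")),
       final_state = list(com1 = c(com1, z_mid[1]), com2 = c(com2, z_mid[2]),
                          theta = th, phi = ph, omega = om, bend = bend),
       t_end = t_offset + p$n_steps * p$dt)
}

# rigid-rod bead positions from saved reduced state, with per-bead noise
regenerate_beads <- function(top, S, z_mid, p, rigid_span, box) {
  n_save <- nrow(S)
  resA <- top$residue_number[top$chain_id == "A"]
  resB <- top$residue_number[top$chain_id == "B"]
  nb <- nrow(top)
  coords <- array(0, dim = c(n_save, nb, 3))
  sd_bead <- function(res) {
    inside <- res >= rigid_span[1] & res <= rigid_span[2]
    ifelse(inside, p$bead_noise$core, p$bead_noise$termini)
  }
  sdA <- sd_bead(resA); sdB <- sd_bead(resB)
  pivot <- if (!is.null(p$kink)) p$kink$pivot else NA
  rod <- function(res, u, bend) {
    nres <- length(res)
    jm <- (nres + 1) / 2
    if (is.na(pivot) || bend < 1e-9) {
      pos <- outer((jm - seq_len(nres)) * p$rise, u)
    } else {
      jp <- which(res == pivot)[1]
      if (is.na(jp)) jp <- round(nres / 2)
      perp <- c(u[2], -u[1], 0)
      if (sqrt(sum(perp^2)) < 1e-9) perp <- c(1, 0, 0)
      u2 <- drop(rotation_about(perp, bend) %*% u)
      j <- seq_len(nres)
      pos <- matrix(0, nres, 3)
      pos[j <= jp, ] <- outer((jp - j[j <= jp]) * p$rise, u)
      pos[j > jp, ] <- outer(-(j[j > jp] - jp) * p$rise, u2)
    }
    sweep(pos, 2, colMeans(pos))
  }
  for (i in seq_len(n_save)) {
    u1 <- sphere2cart(S[i, 5], S[i, 7]); u2 <- sphere2cart(S[i, 6], S[i, 8])
    xyzA <- sweep(rod(resA, u1, S[i, 10]), 2,
                  c(S[i, 1], S[i, 2], z_mid[1]), "+")
    xyzB <- sweep(rod(resB, u2, S[i, 11]), 2,
                  c(S[i, 3], S[i, 4], z_mid[2]), "+")
    noise <- matrix(stats::rnorm(nb * 3), nb, 3) * c(sdA, sdB)
    coords[i, , ] <- rbind(xyzA, xyzB) + noise
  }
  coords
}

#' Generate the deterministic fixture set for the test suite
#'
#' Writes the ten starting structures (both receptors, five
#' orientations) as GRO files, one associating BD trajectory per
#' receptor, and one two-mode (70/30 dwell) trajectory for clustering
#' tests, plus a JSON manifest with seeds and checksums. Structures are
#' seed-independent; trajectories depend on the seed.
#'
#' @param out_dir output directory (created if needed).
#' @param seed base seed; trajectory seeds are derived from it.
#' @param n_steps BD steps per trajectory (default 20000).
#' @return the manifest, invisibly (list with \code{files} and
#'   \code{checksums}).
#' @export
make_test_suite_fixtures <- function(out_dir, seed = 1, n_steps = 20000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (spec in all_system_specs()) {
    b <- build_initial_system(spec)
    f <- file.path(out_dir, sprintf("start_%s_%s.gro", spec$receptor,
                                    spec$orientation))
    write_structure(b$topology, b$frame, f, "gro")
    files <- c(files, f)
  }
  for (r in c("IR", "IGF1R")) {
    b <- build_initial_system(system_spec(r, "O2"))
    pars <- bd_params(seed = seed + match(r, c("IR", "IGF1R")),
                      n_steps = n_steps, save_interval = 100)
    traj <- simulate_bd(b$topology, b$frame, pars)
    f <- file.path(out_dir, sprintf("assoc_%s.trj.tsv", r))
    write_trajectory(traj, f, "tsv")
    files <- c(files, f)
  }
  traj <- two_mode_trajectory("IR", seed = seed + 3,
                              n_frames_per_cycle = c(140, 60), n_cycles = 3)
  f <- file.path(out_dir, "two_mode_IR.trj.tsv")
  write_trajectory(traj, f, "tsv")
  files <- c(files, f)
  manifest <- list(seed = seed, files = basename(files),
                   checksums = as.list(unname(tools::md5sum(files))))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Two-mode dimer trajectory with a planted dwell ratio
#'
#' Alternates an X-like mode (tilted, crossed) and a parallel mode
#' (upright, tight contact) with the given per-cycle frame dwells,
#' yielding a ground-truth population ratio for clustering tests. The
#' system starts already dimerized in the X-like mode so every frame
#' samples one of the two basins.
#'
#' @param receptor "IR" or "IGF1R".
#' @param seed RNG seed.
#' @param n_frames_per_cycle frames in mode A and mode B per cycle
#'   (default c(140, 60), a 70/30 split).
#' @param n_cycles number of cycles.
#' @param save_interval ps between frames.
#' @return an \code{md_trajectory} with
#'   \code{metadata$mode_of_frame} ("X" or "parallel").
#' @export
two_mode_trajectory <- function(receptor = "IR", seed = 1,
                                n_frames_per_cycle = c(140, 60),
                                n_cycles = 3, save_interval = 50) {
  start_spec <- structure(list(receptor = receptor, orientation = "dimer",
                               initial_dhh = 1.15, initial_theta = 35,
                               initial_omega = 30, box = c(20, 20, 4)),
                          class = "system_spec")
  built <- build_initial_system(start_spec)
  dt <- 10
  steps_per_frame <- save_interval / dt
  mode_A <- list(tilt_potential = list(k = 0.05, theta0 = 35),
                 omega_potential = list(k = 0.1, omega0 = 30),
                 association_well = list(depth = 8, r0 = 1.15, width = 0.25))
  mode_B <- list(tilt_potential = list(k = 0.05, theta0 = 5),
                 omega_potential = list(k = 0.1, omega0 = 0),
                 association_well = list(depth = 8, r0 = 0.9, width = 0.25))
  base <- bd_params(seed = seed, dt = dt, save_interval = save_interval,
                    bead_noise = list(core = 0.02, termini = 0.04))
  segments <- list()
  modes <- character(0)
  for (cyc in seq_len(n_cycles)) {
    segments <- c(segments, list(
      list(n_steps = n_frames_per_cycle[1] * steps_per_frame,
           override = mode_A),
      list(n_steps = n_frames_per_cycle[2] * steps_per_frame,
           override = mode_B)))
    modes <- c(modes, rep(c("X", "parallel"), n_frames_per_cycle))
  }
  traj <- simulate_bd_schedule(built$topology, built$frame, base, segments)
  traj$metadata$mode_of_frame <- modes
  traj
}
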