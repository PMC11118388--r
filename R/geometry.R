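#' Fit a helix axis to backbone beads
#'
#' The axis is the first principal component of the backbone-bead
#' coordinates over the given residue span. By default the direction is
#' orientation-fixed to point toward the extracellular side (+z,
#' non-negative z-component), so that reversing bead order leaves the
#' reported axis unchanged; \code{orient = "nc"} instead orients it along
#' increasing residue order (N to C), which is what kink angles need.
#'
#' @param frame an \code{md_frame}.
#' @param topology a \code{bead_topology}.
#' @param chain chain id ("A" or "B").
#' @param span inclusive residue range \code{c(first, last)}.
#' @param orient "z" (default) or "nc" sign convention.
#' @return a \code{helix_axis}: list with \code{centroid} (nm),
#'   \code{direction} (unit vector) and \code{span_residues}.
#' @export
fit_axis <- function(frame, topology, chain, span, orient = c("z", "nc")) {
  orient <- match.arg(orient)
  idx <- select_beads(topology, chain = chain, span = span, bead = "BB")
  if (length(idx) < 3)
    stop("fit_axis needs at least 3 backbone beads in the span (got ",
         length(idx), ")")
  xyz <- frame$coords[idx, , drop = FALSE]
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr), nu = 0, nv = 1)
  u <- drop(sv$v)
  if (orient == "z") {
    if (u[3] < 0) u <- -u
    else if (u[3] == 0) {
      nz <- which(u != 0)[1]
      if (length(nz) && u[nz] < 0) u <- -u
    }
  } else {
    nc <- xyz[nrow(xyz), ] - xyz[1, ]
    if (sum(u * nc) < 0) u <- -u
  }
  structure(list(centroid = ctr, direction = u / sqrt(sum(u^2)),
                 span_residues = span),
            class = "helix_axis")
}

#' Tilt angle of a helix axis relative to the membrane normal
#'
#' theta = arccos(|axis . normal|), folded to [0, 90] degrees. The
#' membrane is built in the xy plane, so the laboratory +z axis is the
#' default normal.
#'
#' @param axis a \code{helix_axis} (or unit 3-vector).
#' @param membrane_normal unit 3-vector (default +z).
#' @return tilt angle in degrees, in [0, 90].
#' @export
tilt_angle <- function(axis, membrane_normal = c(0, 0, 1)) {
  if (abs(sqrt(sum(membrane_normal^2)) - 1) > 1e-8)
    stop("membrane_normal must be a unit vector")
  u <- if (inherits(axis, "helix_axis")) axis$direction else axis
  .rad2deg(acos(min(1, abs(sum(u * membrane_normal)))))
}

#' Crossing angle between two helix axes
#'
#' Omega = arccos(|u1 . u2|), unsigned and folded to [0, 90] degrees
#' (handedness of the packing is not resolved).
#'
#' @param axis1,axis2 \code{helix_axis} objects (or unit 3-vectors).
#' @return crossing angle in degrees, in [0, 90].
#' @export
crossing_angle <- function(axis1, axis2) {
  u1 <- if (inherits(axis1, "helix_axis")) axis1$direction else axis1
  u2 <- if (inherits(axis2, "helix_axis")) axis2$direction else axis2
  .rad2deg(acos(min(1, abs(sum(u1 * u2)))))
}

# minimum-image displacement, applied in the membrane plane (x, y) only:
# helices never wrap in z inside a slab
min_image_xy <- function(d, box) {
  d[1] <- d[1] - box[1] * round(d[1] / box[1])
  d[2] <- d[2] - box[2] * round(d[2] / box[2])
  d
}

#' Inter-helical centre-of-mass distance (d_HH)
#'
#' Euclidean distance between the centroids of the beads of the two
#' measurement spans (equal bead masses), minimum-image corrected in the
#' membrane plane.
#'
#' @param frame an \code{md_frame}.
#' @param topology a \code{bead_topology}.
#' @param span1,span2 residue ranges for chains A and B.
#' @param chains chain ids of the two helices (default c("A", "B")).
#' @return distance in nm.
#' @export
interhelical_distance <- function(frame, topology, span1, span2,
                                  chains = c("A", "B")) {
  i1 <- select_beads(topology, chain = chains[1], span = span1)
  i2 <- select_beads(topology, chain = chains[2], span = span2)
  if (!length(i1) || !length(i2)) stop("empty residue span")
  c1 <- colMeans(frame$coords[i1, , drop = FALSE])
  c2 <- colMeans(frame$coords[i2, , drop = FALSE])
  sqrt(sum(min_image_xy(c2 - c1, frame$box)^2))
}

#' Kink angle at a pivot residue
#'
#' Angle between the axis fitted to residues [pivot - halfspan, pivot]
#' and to [pivot, pivot + halfspan], both oriented N-to-C, in [0, 180]
#' degrees. A straight helix gives 0.
#'
#' @param frame an \code{md_frame}.
#' @param topology a \code{bead_topology}.
#' @param chain chain id.
#' @param pivot pivot residue number (e.g. 960 for IR, 941 for IGF1R).
#' @param halfspan residues on each side of the pivot (>= 3; default 5).
#' @return kink angle in degrees.
#' @export
kink_angle <- function(frame, topology, chain, pivot, halfspan = 5) {
  if (halfspan < 3) stop("halfspan must be >= 3")
  rn <- topology$residue_number[topology$chain_id == chain]
  if (pivot - halfspan < min(rn) || pivot + halfspan > max(rn))
    stop("kink window [", pivot - halfspan, ", ", pivot + halfspan,
         "] lies outside chain ", chain, " residues ", min(rn), "-", max(rn))
  a1 <- fit_axis(frame, topology, chain, c(pivot - halfspan, pivot), "nc")
  a2 <- fit_axis(frame, topology, chain, c(pivot, pivot + halfspan), "nc")
  d <- max(-1, min(1, sum(a1$direction * a2$direction)))
  .rad2deg(acos(d))
}

#' Crossing point of two helix axes
#'
#' Computes the mutual closest approach of the two (infinite) axis lines
#' and reports the residue whose backbone bead is nearest the mid-point
#' of the closest-approach segment, together with the line-line distance.
#' No residue is reported when the lines pass farther apart than
#' \code{bound} (or when the axes are exactly parallel).
#'
#' @param axis1,axis2 \code{helix_axis} objects.
#' @param frame the \code{md_frame} the axes were fitted to.
#' @param topology a \code{bead_topology}.
#' @param bound proximity bound in nm (default 1.5, just above the 1.3 nm
#'   dimerization criterion so dimerized frames always report a residue).
#' @return list with \code{residue} (residue number or NA),
#'   \code{chain} (chain of that residue or NA), \code{min_approach} (nm)
#'   and \code{point} (mid-point, or NA for parallel axes).
#' @export
crossing_point <- function(axis1, axis2, frame, topology, bound = 1.5) {
  p1 <- axis1$centroid; u1 <- axis1$direction
  p2 <- axis2$centroid; u2 <- axis2$direction
  w <- p1 - p2
  a <- sum(u1 * u1); b <- sum(u1 * u2); c_ <- sum(u2 * u2)
  d <- sum(u1 * w); e <- sum(u2 * w)
  denom <- a * c_ - b * b
  if (denom < 1e-12) {
    # exactly (or numerically) parallel: perpendicular distance, no residue
    perp <- w - sum(w * u1) * u1
    return(list(residue = NA_integer_, chain = NA_character_,
                min_approach = sqrt(sum(perp^2)), point = rep(NA_real_, 3)))
  }
  t1 <- (b * e - c_ * d) / denom
  t2 <- (a * e - b * d) / denom
  q1 <- p1 + t1 * u1
  q2 <- p2 + t2 * u2
  min_approach <- sqrt(sum((q1 - q2)^2))
  if (min_approach > bound)
    return(list(residue = NA_integer_, chain = NA_character_,
                min_approach = min_approach, point = (q1 + q2) / 2))
  mid <- (q1 + q2) / 2
  bb <- select_beads(topology, bead = "BB")
  d2 <- colSums((t(frame$coords[bb, , drop = FALSE]) - mid)^2)
  k <- bb[which.min(d2)]
  list(residue = topology$residue_number[k], chain = topology$chain_id[k],
       min_approach = min_approach, point = mid)
}

# ---- Kabsch superposition ------------------------------------------------

# optimal proper rotation (det +1): right-multiplying centred row-vector
# coordinates P by this matrix best maps them onto centred Q
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Least-squares RMSD after optimal superposition (Kabsch)
#'
#' Translates both selections to their centroids, finds the optimal
#' proper rotation by SVD (determinant +1 enforced, so reflections are
#' never used), and returns the residual root-mean-square deviation.
#'
#' @param ref,mov \code{md_frame}s (or n x 3 coordinate matrices).
#' @param selection bead indices used for the fit (>= 3); NULL uses all.
#' @return RMSD in nm.
#' @export
kabsch_rmsd <- function(ref, mov, selection = NULL) {
  R <- if (inherits(ref, "md_frame")) ref$coords else as.matrix(ref)
  M <- if (inherits(mov, "md_frame")) mov$coords else as.matrix(mov)
  if (!is.null(selection)) {
    R <- R[selection, , drop = FALSE]
    M <- M[selection, , drop = FALSE]
  }
  if (nrow(R) != nrow(M))
    stop("selections differ in size (", nrow(R), " vs ", nrow(M), ")")
  if (nrow(R) < 3) stop("need at least 3 beads for superposition")
  Rc <- sweep(R, 2, colMeans(R))
  Mc <- sweep(M, 2, colMeans(M))
  rot <- kabsch_rotation(Mc, Rc)
  fit <- Mc %*% rot
  sqrt(mean(rowSums((fit - Rc)^2)))
}

# superpose mov onto ref over `selection`, returning all transformed rows
kabsch_superpose <- function(ref, mov, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(ref))
  Rc <- colMeans(ref[selection, , drop = FALSE])
  Mc <- colMeans(mov[selection, , drop = FALSE])
  rot <- kabsch_rotation(sweep(mov[selection, , drop = FALSE], 2, Mc),
                         sweep(ref[selection, , drop = FALSE], 2, Rc))
  sweep(sweep(mov, 2, Mc) %*% rot, 2, Rc, "+")
}

#' Per-frame pair geometry over a trajectory
#'
#' Computes, for every frame: the inter-helical distance d_HH, both tilt
#' angles, the crossing angle, both kink angles, and the crossing-point
#' residue and line-line closest approach. Residue spans and kink pivots
#' default to the receptor preset inferred from the topology's residue
#' range, and can all be overridden.
#'
#' @param trajectory an \code{md_trajectory} with chains A and B.
#' @param preset optional preset list from \code{\link{tmd_preset}}.
#' @param dhh_span,tilt_span residue ranges \code{c(first, last)} used
#'   for d_HH and the axis fits (same numbering on both chains).
#' @param kink_pivot pivot residue for the kink angle.
#' @param kink_halfspan residues each side of the pivot (default 5).
#' @param membrane_normal unit vector (default +z).
#' @param proximity_bound crossing-point bound in nm (default 1.5).
#' @return a data frame of class \code{pair_geometry} with columns
#'   \code{time, dhh, theta1, theta2, omega, kink1, kink2,
#'   crossing_residue, min_approach}.
#' @export
pair_geometry <- function(trajectory, preset = NULL,
                          dhh_span = preset$dhh_span,
                          tilt_span = preset$tilt_span,
                          kink_pivot = preset$kink_pivot,
                          kink_halfspan = 5,
                          membrane_normal = c(0, 0, 1),
                          proximity_bound = 1.5) {
  top <- trajectory$topology
  if (is.null(preset) && (is.null(dhh_span) || is.null(tilt_span)))
    preset <- infer_preset(top)
  if (is.null(dhh_span)) dhh_span <- preset$dhh_span
  if (is.null(tilt_span)) tilt_span <- preset$tilt_span
  if (is.null(kink_pivot)) kink_pivot <- preset$kink_pivot
  dhh_span <- as_span(dhh_span); tilt_span <- as_span(tilt_span)
  nf <- n_frames(trajectory)
  out <- data.frame(time = trajectory$times, dhh = NA_real_,
                    theta1 = NA_real_, theta2 = NA_real_, omega = NA_real_,
                    kink1 = NA_real_, kink2 = NA_real_,
                    crossing_residue = NA_integer_, min_approach = NA_real_)
  kink_ok <- !is.null(kink_pivot) && !is.na(kink_pivot)  # NA disables kinks
  for (i in seq_len(nf)) {
    fr <- get_frame(trajectory, i)
    a1 <- fit_axis(fr, top, "A", tilt_span)
    a2 <- fit_axis(fr, top, "B", tilt_span)
    out$dhh[i] <- interhelical_distance(fr, top, dhh_span, dhh_span)
    out$theta1[i] <- tilt_angle(a1, membrane_normal)
    out$theta2[i] <- tilt_angle(a2, membrane_normal)
    out$omega[i] <- crossing_angle(a1, a2)
    if (kink_ok) {
      out$kink1[i] <- kink_angle(fr, top, "A", kink_pivot, kink_halfspan)
      out$kink2[i] <- kink_angle(fr, top, "B", kink_pivot, kink_halfspan)
    }
    cp <- crossing_point(a1, a2, fr, top, bound = proximity_bound)
    out$crossing_residue[i] <- cp$residue
    out$min_approach[i] <- cp$min_approach
  }
  class(out) <- c("pair_geometry", "data.frame")
  out
}

as_span <- function(s) {
  if (is.list(s)) c(s$first, s$last) else as.numeric(s)
}

# pick the receptor preset whose construct range matches the topology
infer_preset <- function(topology) {
  rng <- range(topology$residue_number)
  for (r in c("IR", "IGF1R")) {
    p <- tmd_preset(r)
    if (p$residues$first == rng[1] && p$residues$last == rng[2]) return(p)
  }
  stop("cannot infer receptor preset from residue range ", rng[1], "-",
       rng[2], "; pass dhh_span/tilt_span explicitly")
}
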