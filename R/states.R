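#' Detect dimerized frames from a d_HH series
#'
#' A frame is dimerized when the inter-helical distance is at or below
#' the cutoff ("within 1.3 nm" read inclusively). Dwell segments are
#' computed by run-length encoding; an optional minimum-dwell filter can
#' suppress short flickers (off by default so no transient dissociation
#' is ever hidden).
#'
#' @param dhh_series per-frame d_HH values in nm.
#' @param cutoff dimerization cutoff in nm (default 1.3).
#' @param times optional frame times in ps.
#' @param min_dwell minimum segment length in frames (default 1 = no
#'   filtering); shorter segments are merged into their neighbours.
#' @return a \code{state_series}: list with \code{times},
#'   \code{dimerized} (logical), \code{first_passage_frame} (index or NA)
#'   and \code{dwell_segments} (data frame start/end/state partitioning
#'   the frame range).
#' @export
detect_dimerization <- function(dhh_series, cutoff = 1.3, times = NULL,
                                min_dwell = 1) {
  if (!length(dhh_series)) stop("empty d_HH series")
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (anyNA(dhh_series))
    stop("NaN/NA d_HH at frame ", which(is.na(dhh_series))[1])
  dim_state <- dhh_series <= cutoff
  if (min_dwell > 1 && length(dim_state) > 1) {
    r <- rle(dim_state)
    while (any(r$lengths < min_dwell) && length(r$lengths) > 1) {
      k <- which(r$lengths < min_dwell)[1]
      r$values[k] <- !r$values[k]
      r <- rle(inverse.rle(r))
    }
    dim_state <- inverse.rle(r)
  }
  fp <- which(dim_state)[1]
  r <- rle(dim_state)
  ends <- cumsum(r$lengths)
  segs <- data.frame(start = c(1L, utils::head(ends, -1) + 1L), end = ends,
                     state = ifelse(r$values, "dimerized", "dissociated"),
                     stringsAsFactors = FALSE)
  structure(list(times = if (is.null(times)) seq_along(dhh_series) else times,
                 dimerized = dim_state,
                 first_passage_frame = if (is.na(fp)) NA_integer_ else fp,
                 dwell_segments = segs),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf("State series: %d frames, %.1f%% dimerized, first passage %s\n",
              length(x$dimerized), 100 * mean(x$dimerized),
              ifelse(is.na(x$first_passage_frame), "never",
                     paste0("frame ", x$first_passage_frame))))
  invisible(x)
}

# deterministic, roughly uniform spherical quadrature (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area of CG beads
#'
#' Each bead is expanded by the probe radius and covered with a
#' deterministic spherical quadrature; a quadrature point is exposed if
#' it lies outside every other selected bead's expanded sphere. The SASA
#' is the summed exposed area.
#'
#' @param frame an \code{md_frame}.
#' @param topology a \code{bead_topology} supplying per-bead radii (nm).
#' @param selection bead indices to include; NULL = all beads.
#' @param probe probe radius in nm (default 0.185, about half a CG water
#'   bead).
#' @param n_points quadrature points per bead (>= 64; default 960).
#' @return total SASA in nm^2 (0 for an empty selection).
#' @export
shrake_rupley_sasa <- function(frame, topology, selection = NULL,
                               probe = 0.185, n_points = 960) {
  if (n_points < 64) stop("n_points must be >= 64")
  if (probe < 0) stop("probe radius must be >= 0")
  if (is.null(selection)) selection <- seq_len(nrow(topology))
  if (!length(selection)) return(0)
  xyz <- frame$coords[selection, , drop = FALSE]
  if (any(topology$bead_radius[selection] <= 0))
    stop("all bead radii must be > 0")
  rad <- topology$bead_radius[selection] + probe
  pts <- fibonacci_sphere(n_points)
  n <- length(selection)
  total <- 0
  for (i in seq_len(n)) {
    p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    d2c <- colSums((t(xyz) - xyz[i, ])^2)
    near <- which(d2c < (rad + rad[i])^2 & seq_len(n) != i)
    for (j in near) {
      if (!any(exposed)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 > rad[j]^2
    }
    total <- total + 4 * pi * rad[i]^2 * sum(exposed) / n_points
  }
  total
}

#' Buried surface area between two chains
#'
#' BSA = SASA(A alone) + SASA(B alone) - SASA(A and B together), clipped
#' at zero after a quadrature-tolerance check.
#'
#' @param frame an \code{md_frame}.
#' @param topology a \code{bead_topology}.
#' @param chainA,chainB chain ids (must be disjoint).
#' @param probe probe radius in nm.
#' @param n_points quadrature points per bead.
#' @return list with \code{sasa_A}, \code{sasa_B}, \code{sasa_AB} and
#'   \code{bsa}, all in nm^2.
#' @export
buried_surface_area <- function(frame, topology, chainA = "A", chainB = "B",
                                probe = 0.185, n_points = 960) {
  ia <- select_beads(topology, chain = chainA)
  ib <- select_beads(topology, chain = chainB)
  if (length(intersect(ia, ib))) stop("chains must be disjoint")
  sa <- shrake_rupley_sasa(frame, topology, ia, probe, n_points)
  sb <- shrake_rupley_sasa(frame, topology, ib, probe, n_points)
  sab <- shrake_rupley_sasa(frame, topology, c(ia, ib), probe, n_points)
  bsa <- sa + sb - sab
  tol <- 4 * pi * max(topology$bead_radius + probe)^2 / n_points *
    length(c(ia, ib))
  if (bsa < -tol)
    stop("BSA more negative than quadrature tolerance; check radii/probe")
  list(sasa_A = sa, sasa_B = sb, sasa_AB = sab, bsa = max(bsa, 0))
}

#' Buried-surface-area time series over a trajectory
#'
#' @param trajectory an \code{md_trajectory}.
#' @param frames frame indices to evaluate (default all).
#' @param probe probe radius in nm.
#' @param n_points quadrature points per bead.
#' @return data frame with columns \code{time, sasa_A, sasa_B, sasa_AB,
#'   bsa} (nm^2) and attribute \code{probe_radius}.
#' @export
surface_series <- function(trajectory, frames = seq_len(n_frames(trajectory)),
                           probe = 0.185, n_points = 960) {
  rows <- lapply(frames, function(i) {
    b <- buried_surface_area(get_frame(trajectory, i), trajectory$topology,
                             probe = probe, n_points = n_points)
    data.frame(time = trajectory$times[i], sasa_A = b$sasa_A,
               sasa_B = b$sasa_B, sasa_AB = b$sasa_AB, bsa = b$bsa)
  })
  out <- do.call(rbind, rows)
  attr(out, "probe_radius") <- probe
  out
}

#' Residue-pair contact map over dimerized frames
#'
#' Mean, over dimerized frames only, of the distance between the
#' centres of mass of every residue pair (all beads of the residue,
#' minimum-image corrected in the membrane plane).
#'
#' @param trajectory an \code{md_trajectory}.
#' @param state a \code{state_series} from \code{\link{detect_dimerization}}
#'   (frame count must match), or NULL to use all frames.
#' @param spanA,spanB residue ranges for the two chains; default the full
#'   chain ranges.
#' @return a \code{contact_map}: matrix (chain A residues x chain B
#'   residues, nm) with attributes \code{frame_count}, \code{resA},
#'   \code{resB}.
#' @export
contact_map <- function(trajectory, state = NULL, spanA = NULL, spanB = NULL) {
  top <- trajectory$topology
  keep <- if (is.null(state)) seq_len(n_frames(trajectory)) else {
    if (length(state$dimerized) != n_frames(trajectory))
      stop("state series length does not match trajectory")
    which(state$dimerized)
  }
  if (!length(keep))
    stop("no dimerized frames; check the d_HH threshold before mapping contacts")
  resA <- sort(unique(top$residue_number[top$chain_id == "A"]))
  resB <- sort(unique(top$residue_number[top$chain_id == "B"]))
  if (!is.null(spanA)) resA <- resA[resA >= spanA[1] & resA <= spanA[2]]
  if (!is.null(spanB)) resB <- resB[resB >= spanB[1] & resB <= spanB[2]]
  idxA <- lapply(resA, function(r) which(top$chain_id == "A" &
                                           top$residue_number == r))
  idxB <- lapply(resB, function(r) which(top$chain_id == "B" &
                                           top$residue_number == r))
  acc <- matrix(0, length(resA), length(resB))
  res_com <- function(coords_f, ii) {
    if (length(ii) == 1) coords_f[ii, ]
    else colMeans(coords_f[ii, , drop = FALSE])
  }
  for (f in keep) {
    box <- trajectory$box[f, ]
    coords_f <- trajectory$coords[f, , , drop = TRUE]
    comA <- t(vapply(idxA, res_com, numeric(3), coords_f = coords_f))
    comB <- t(vapply(idxB, res_com, numeric(3), coords_f = coords_f))
    dx <- outer(comA[, 1], comB[, 1], "-")
    dy <- outer(comA[, 2], comB[, 2], "-")
    dz <- outer(comA[, 3], comB[, 3], "-")
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    acc <- acc + sqrt(dx^2 + dy^2 + dz^2)
  }
  m <- acc / length(keep)
  dimnames(m) <- list(resA, resB)
  structure(m, class = c("contact_map", "matrix"), frame_count = length(keep),
            resA = resA, resB = resB)
}

#' Plot a contact map as a heat map
#' @param x a \code{contact_map}.
#' @param ... passed to \code{graphics::image}.
#' @export
plot.contact_map <- function(x, ...) {
  resA <- attr(x, "resA"); resB <- attr(x, "resB")
  graphics::image(resA, resB, unclass(x), xlab = "chain A residue",
                  ylab = "chain B residue",
                  col = grDevices::hcl.colors(64, "viridis", rev = TRUE), ...)
  invisible(x)
}

#' Packing-mode classification thresholds
#'
#' Operational thresholds separating the packing modes: X-shaped above
#' \code{omega_x} (crossed axes), parallel at or below \code{omega_p}
#' with tight contact (d_HH below \code{dhh_parallel_max}), V-shaped at
#' small crossing angle but with a pronounced kink and d_HH in the
#' X/V-range.
#'
#' @param omega_x crossing-angle threshold for X-shaped (deg, default 15).
#' @param omega_p crossing-angle threshold for parallel (deg, default 5).
#' @param kink_min minimum kink angle for V-shaped (deg, default 15).
#' @param dhh_parallel_max d_HH upper bound for parallel (nm, default 1.0).
#' @param dhh_dimer_max dimer criterion (nm, default 1.3).
#' @return a named list of thresholds.
#' @export
packing_thresholds <- function(omega_x = 15, omega_p = 5, kink_min = 15,
                               dhh_parallel_max = 1.0, dhh_dimer_max = 1.3) {
  list(omega_x = omega_x, omega_p = omega_p, kink_min = kink_min,
       dhh_parallel_max = dhh_parallel_max, dhh_dimer_max = dhh_dimer_max)
}

#' Classify the packing mode of dimerized frames
#'
#' Rule-based labels: "X" when the crossing angle exceeds
#' \code{omega_x} and a crossing residue is localized; "parallel" when
#' the crossing angle is at most \code{omega_p} and d_HH is below
#' \code{dhh_parallel_max}; "V" when the crossing angle is at most
#' \code{omega_x} but a kink above \code{kink_min} is present and d_HH
#' lies in the X/V contact range; otherwise "unclassified". Non-dimerized
#' rows are an error: packing modes are defined only for dimers.
#'
#' @param geometry a \code{pair_geometry} data frame (or single row).
#' @param thresholds from \code{\link{packing_thresholds}}.
#' @return character vector of labels, one per row.
#' @export
classify_packing <- function(geometry, thresholds = packing_thresholds()) {
  g <- as.data.frame(geometry)
  th <- thresholds
  if (any(g$dhh > th$dhh_dimer_max))
    stop("classify_packing applies to dimerized frames only (d_HH <= ",
         th$dhh_dimer_max, " nm); filter with detect_dimerization first")
  kink <- pmax(if (is.null(g$kink1)) 0 else ifelse(is.na(g$kink1), 0, g$kink1),
               if (is.null(g$kink2)) 0 else ifelse(is.na(g$kink2), 0, g$kink2))
  lab <- rep("unclassified", nrow(g))
  lab[g$omega > th$omega_x & !is.na(g$crossing_residue)] <- "X"
  lab[lab == "unclassified" & g$omega <= th$omega_p &
        g$dhh < th$dhh_parallel_max] <- "parallel"
  lab[lab == "unclassified" & g$omega <= th$omega_x & kink > th$kink_min &
        g$dhh >= th$dhh_parallel_max & g$dhh <= th$dhh_dimer_max] <- "V"
  lab
}

#' Per-frame state table (dimerization + packing mode)
#'
#' Combines \code{\link{detect_dimerization}} and
#' \code{\link{classify_packing}} into one per-frame table; dissociated
#' frames get packing mode "none".
#'
#' @param geometry a \code{pair_geometry} data frame.
#' @param cutoff dimerization cutoff in nm.
#' @param thresholds packing thresholds.
#' @return list with \code{state} (the \code{state_series}) and
#'   \code{table} (data frame time, dhh, dimerized, mode).
#' @export
state_table <- function(geometry, cutoff = 1.3,
                        thresholds = packing_thresholds()) {
  st <- detect_dimerization(geometry$dhh, cutoff = cutoff,
                            times = geometry$time)
  mode <- rep("none", nrow(geometry))
  if (any(st$dimerized))
    mode[st$dimerized] <- classify_packing(geometry[st$dimerized, ,
                                                    drop = FALSE],
                                           thresholds)
  list(state = st,
       table = data.frame(time = geometry$time, dhh = geometry$dhh,
                          dimerized = st$dimerized, mode = mode,
                          stringsAsFactors = FALSE))
}
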