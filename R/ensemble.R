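#' Probability histogram of an angle sample
#'
#' Fixed-width bins with the half-open convention [edge, edge): a value
#' exactly on a bin edge belongs to the bin on its right. Values outside
#' the range are counted into an overflow tally (reported, never silently
#' dropped); probabilities are normalized over the in-range counts.
#'
#' @param values numeric sample (degrees).
#' @param bin_width bin width in degrees (default 2.5).
#' @param range \code{c(lo, hi)} histogram range (default c(0, 90)).
#' @return list with \code{bin_centers}, \code{counts},
#'   \code{probability} (sums to 1 over bins) and \code{overflow}.
#' @export
angle_histogram <- function(values, bin_width = 2.5, range = c(0, 90)) {
  if (!length(values)) stop("empty sample")
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (range[2] <= range[1]) stop("invalid range")
  nb <- ceiling((range[2] - range[1]) / bin_width - 1e-9)
  idx <- floor((values - range[1]) / bin_width) + 1
  inside <- values >= range[1] & idx <= nb
  overflow <- sum(!inside)
  counts <- tabulate(idx[inside], nbins = nb)
  if (!sum(counts)) stop("all values fall outside the histogram range")
  list(bin_centers = range[1] + (seq_len(nb) - 0.5) * bin_width,
       counts = counts,
       probability = counts / sum(counts),
       overflow = overflow)
}

#' Boltzmann inversion of a binned probability
#'
#' U_i = -k_B T ln(P_i) for occupied bins, shifted so the minimum over
#' occupied bins is zero. Empty bins are undefined (NA), never clamped to
#' a cap: caps distort minima searches.
#'
#' @param probability per-bin probabilities (>= 0).
#' @param temperature temperature in K (default 300; k_B T = 0.5961
#'   kcal/mol).
#' @return free energy per bin in kcal/mol (NA for empty bins).
#' @export
boltzmann_invert <- function(probability, temperature = 300) {
  if (any(probability < 0)) stop("probabilities must be >= 0")
  if (all(probability == 0)) stop("all-zero probabilities")
  u <- rep(NA_real_, length(probability))
  occ <- probability > 0
  u[occ] <- -kBT(temperature) * log(probability[occ])
  u - min(u, na.rm = TRUE)
}

#' Free-energy profile with replicate averaging
#'
#' Computes a Boltzmann-inversion free-energy profile per replicate and
#' averages the profiles bin-wise (mean and sd), following the
#' free-energies-then-average convention rather than pooling histograms.
#' A bin empty in any replicate is undefined in the mean. The reported
#' \code{probability} is the pooled-sample histogram; \code{free_energy}
#' is the replicate mean re-shifted so its occupied minimum is zero.
#'
#' @param samples list of numeric samples, one per replicate (degrees).
#' @param variable label, "theta" or "omega".
#' @param bin_width bin width in degrees (default 2.5).
#' @param range histogram range (default c(0, 90)).
#' @param temperature temperature in K (default 300).
#' @return a \code{pmf_profile}: data frame with columns
#'   \code{bin_center, probability, free_energy, replicate_mean,
#'   replicate_sd}, plus attributes \code{variable}, \code{temperature},
#'   \code{n_replicates}, \code{minimum} (bin center of the free-energy
#'   minimum).
#' @export
pmf_with_replicates <- function(samples, variable = c("theta", "omega"),
                                bin_width = 2.5, range = c(0, 90),
                                temperature = 300) {
  variable <- match.arg(variable)
  if (!is.list(samples)) samples <- list(samples)
  if (!length(samples)) stop("need at least one replicate")
  for (k in seq_along(samples))
    if (!length(samples[[k]])) stop("replicate ", k, " is empty")
  hists <- lapply(samples, angle_histogram, bin_width = bin_width,
                  range = range)
  U <- vapply(hists, function(h) boltzmann_invert(h$probability, temperature),
              numeric(length(hists[[1]]$probability)))
  U <- matrix(U, ncol = length(samples))
  rep_mean <- rowMeans(U)                       # NA where any replicate empty
  rep_sd <- apply(U, 1, stats::sd)
  if (length(samples) == 1) rep_sd <- rep(0, nrow(U))
  pooled <- angle_histogram(unlist(samples), bin_width, range)
  fe <- rep_mean - min(rep_mean, na.rm = TRUE)
  out <- data.frame(bin_center = hists[[1]]$bin_centers,
                    probability = pooled$probability,
                    free_energy = fe,
                    replicate_mean = rep_mean,
                    replicate_sd = rep_sd)
  attr(out, "variable") <- variable
  attr(out, "temperature") <- temperature
  attr(out, "n_replicates") <- length(samples)
  attr(out, "minimum") <- out$bin_center[which.min(fe)]
  class(out) <- c("pmf_profile", "data.frame")
  out
}

#' Per-residue root-mean-square fluctuation
#'
#' Each frame is superposed (Kabsch) onto a reference over the
#' align-span backbone beads; the reference is the mean structure after
#' one initial alignment pass to the first frame. RMSF per backbone bead
#' is the root mean square of its displacement from its time-averaged
#' position.
#'
#' @param trajectory an \code{md_trajectory} (>= 2 frames).
#' @param chain chain id.
#' @param align_span residue range used for the superposition (default:
#'   full chain).
#' @return data frame with columns \code{residue}, \code{rmsf} (nm) and
#'   \code{chain}.
#' @export
rmsf <- function(trajectory, chain = "A", align_span = NULL) {
  nf <- n_frames(trajectory)
  if (nf < 2) stop("RMSF needs at least 2 frames")
  top <- trajectory$topology
  bb <- select_beads(top, chain = chain, bead = "BB")
  if (is.null(align_span))
    align_span <- range(top$residue_number[top$chain_id == chain])
  fit_sel_global <- select_beads(top, chain = chain, span = align_span,
                                 bead = "BB")
  fit_sel <- match(fit_sel_global, bb)
  X <- array(0, dim = c(nf, length(bb), 3))
  ref <- trajectory$coords[1, bb, , drop = TRUE]
  for (i in seq_len(nf))                     # pass 1: align to first frame
    X[i, , ] <- kabsch_superpose(ref, trajectory$coords[i, bb, , drop = TRUE],
                                 fit_sel)
  mean_struct <- apply(X, c(2, 3), mean)
  for (i in seq_len(nf))                     # pass 2: align to mean
    X[i, , ] <- kabsch_superpose(mean_struct,
                                 trajectory$coords[i, bb, , drop = TRUE],
                                 fit_sel)
  mean2 <- apply(X, c(2, 3), mean)
  dev2 <- sweep(X, c(2, 3), mean2)^2
  msf <- apply(dev2, 2, function(m) mean(rowSums(matrix(m, nrow = nf))))
  data.frame(residue = top$residue_number[bb], rmsf = sqrt(msf),
             chain = chain, stringsAsFactors = FALSE)
}

#' RMSF averaged over replicate trajectories
#'
#' @param trajectories list of \code{md_trajectory} replicates sharing a
#'   topology.
#' @param chain chain id.
#' @param align_span residue range for the superposition.
#' @return data frame with \code{residue}, \code{replicate_mean},
#'   \code{replicate_sd} (nm) and \code{chain}.
#' @export
rmsf_with_replicates <- function(trajectories, chain = "A",
                                 align_span = NULL) {
  profs <- lapply(trajectories, rmsf, chain = chain, align_span = align_span)
  m <- vapply(profs, function(p) p$rmsf, numeric(nrow(profs[[1]])))
  m <- matrix(m, ncol = length(profs))
  data.frame(residue = profs[[1]]$residue,
             replicate_mean = rowMeans(m),
             replicate_sd = if (ncol(m) > 1) apply(m, 1, stats::sd) else 0,
             chain = chain, stringsAsFactors = FALSE)
}

#' Summary of a free-energy profile
#'
#' @param object a \code{pmf_profile}.
#' @param basin_depth basin width is reported at this depth above the
#'   minimum (kcal/mol, default 1).
#' @param ... unused.
#' @return list with the minimum location (deg), its free energy, and the
#'   width (deg) of the basin within \code{basin_depth} of the minimum.
#' @export
summary.pmf_profile <- function(object, basin_depth = 1, ...) {
  fe <- object$free_energy
  kmin <- which.min(fe)
  in_basin <- !is.na(fe) & fe <= fe[kmin] + basin_depth
  bw <- object$bin_center[2] - object$bin_center[1]
  list(variable = attr(object, "variable"),
       minimum = object$bin_center[kmin],
       minimum_free_energy = fe[kmin],
       basin_width = sum(in_basin) * bw,
       temperature = attr(object, "temperature"))
}
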