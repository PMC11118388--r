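#' Pairwise superposition RMSD matrix
#'
#' Symmetric matrix of Kabsch RMSDs between every pair of frames over a
#' bead selection (default: backbone beads of both chains jointly, the
#' dimer treated as one rigid body).
#'
#' @param trajectory an \code{md_trajectory} (or list of \code{md_frame}).
#' @param selection bead indices; NULL = all backbone beads.
#' @param frames frame indices to include (default all).
#' @return symmetric matrix in nm with zero diagonal.
#' @export
pairwise_rmsd <- function(trajectory, selection = NULL, frames = NULL) {
  if (inherits(trajectory, "md_trajectory")) {
    if (is.null(frames)) frames <- seq_len(n_frames(trajectory))
    if (is.null(selection))
      selection <- select_beads(trajectory$topology, bead = "BB")
    coords <- lapply(frames, function(i)
      trajectory$coords[i, selection, , drop = TRUE])
  } else {
    coords <- lapply(trajectory, function(f)
      if (is.null(selection)) f$coords else f$coords[selection, , drop = FALSE])
  }
  n <- length(coords)
  if (n < 2) stop("need at least 2 frames")
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- kabsch_rmsd(coords[[i]], coords[[j]])
    }
  }
  m
}

#' GROMOS (Daura) neighbor-counting clustering
#'
#' Iteratively: count, for every unassigned frame, its unassigned
#' neighbours within the RMSD cutoff; the frame with the most neighbours
#' becomes a cluster centre and is removed together with its neighbours;
#' repeat until every frame is assigned. Neighbour-count ties are broken
#' by the lowest frame index. Clusters are relabelled in order of
#' descending population.
#'
#' @param rmsd_matrix square symmetric non-negative matrix (nm).
#' @param cutoff neighbour cutoff in nm (default 0.9, inclusive).
#' @return a \code{cluster_result}: list with \code{labels} (cluster id
#'   per frame), \code{populations} (percent, descending),
#'   \code{centers} (frame index per cluster), \code{cutoff} and
#'   \code{rmsd_matrix_digest} (checksum for provenance).
#' @export
daura_cluster <- function(rmsd_matrix, cutoff = 0.9) {
  m <- as.matrix(rmsd_matrix)
  if (nrow(m) != ncol(m)) stop("RMSD matrix must be square")
  if (max(abs(m - t(m))) > 1e-9) stop("RMSD matrix must be symmetric")
  if (any(m < 0)) stop("RMSD matrix must be non-negative")
  n <- nrow(m)
  adj <- m <= cutoff
  diag(adj) <- TRUE
  labels <- rep(NA_integer_, n)
  centers <- integer(0)
  k <- 0L
  unassigned <- rep(TRUE, n)
  while (any(unassigned)) {
    counts <- rowSums(adj[, unassigned, drop = FALSE])
    counts[!unassigned] <- -1L
    center <- which.max(counts)          # ties -> lowest index
    k <- k + 1L
    members <- which(unassigned & adj[center, ])
    labels[members] <- k
    centers[k] <- center
    unassigned[members] <- FALSE
  }
  pops <- 100 * tabulate(labels, k) / n
  ord <- order(-pops, centers)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  structure(list(labels = relabel[labels],
                 populations = pops[ord],
                 centers = centers[ord],
                 cutoff = cutoff,
                 rmsd_matrix_digest = rmsd_digest(m)),
            class = "cluster_result")
}

rmsd_digest <- function(m) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(as.numeric(signif(m, 10)), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Daura clustering at %.2f nm: %d clusters over %d frames\n",
              x$cutoff, length(x$populations), length(x$labels)))
  show <- utils::head(seq_along(x$populations), 5)
  for (k in show)
    cat(sprintf("  C%d: %.1f%% (center frame %d)\n", k, x$populations[k],
                x$centers[k]))
  invisible(x)
}

#' Cluster the dimerized frames of a trajectory
#'
#' Restricts the trajectory to dimerized frames (optionally strided),
#' clusters them with \code{\link{daura_cluster}} on backbone-bead
#' superposition RMSDs of the whole dimer, and summarizes each cluster's
#' geometry. Representatives can be written out as structure files.
#'
#' @param trajectory an \code{md_trajectory}.
#' @param state a \code{state_series}; frames with
#'   \code{state$dimerized} are clustered.
#' @param selection bead indices used for the RMSD (default backbone
#'   beads of both chains).
#' @param cutoff RMSD cutoff in nm (default 0.9).
#' @param stride keep every stride-th dimerized frame (default 1).
#' @param geometry optional \code{pair_geometry} for per-cluster mean
#'   theta/omega/d_HH.
#' @param representatives_dir if non-NULL, write each cluster centre as a
#'   GRO file into this directory.
#' @return list with \code{clusters} (a \code{cluster_result}),
#'   \code{frame_indices} (trajectory frames clustered),
#'   \code{summary} (per-cluster data frame: population, center frame,
#'   and mean dhh/theta/omega when geometry is given) and
#'   \code{representative_files}.
#' @export
cluster_dimer_states <- function(trajectory, state, selection = NULL,
                                 cutoff = 0.9, stride = 1, geometry = NULL,
                                 representatives_dir = NULL) {
  idx <- which(state$dimerized)
  if (length(idx) < 2) stop("need at least 2 dimerized frames to cluster")
  idx <- idx[seq(1, length(idx), by = stride)]
  m <- pairwise_rmsd(trajectory, selection = selection, frames = idx)
  cl <- daura_cluster(m, cutoff = cutoff)
  nk <- length(cl$populations)
  summ <- data.frame(cluster = seq_len(nk),
                     population = cl$populations,
                     center_frame = idx[cl$centers])
  if (!is.null(geometry)) {
    for (col in c("dhh", "theta1", "theta2", "omega")) {
      summ[[paste0("mean_", col)]] <- vapply(seq_len(nk), function(k)
        mean(geometry[[col]][idx[cl$labels == k]]), numeric(1))
    }
  }
  rep_files <- character(0)
  if (!is.null(representatives_dir)) {
    dir.create(representatives_dir, recursive = TRUE, showWarnings = FALSE)
    rep_files <- vapply(seq_len(nk), function(k) {
      f <- file.path(representatives_dir, sprintf("cluster_%02d.gro", k))
      write_structure(trajectory$topology,
                      get_frame(trajectory, idx[cl$centers[k]]), f, "gro")
      f
    }, character(1))
  }
  list(clusters = cl, frame_indices = idx, summary = summ,
       representative_files = rep_files)
}
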