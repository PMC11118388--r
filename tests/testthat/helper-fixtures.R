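# Shared fixture builders and independent oracles.

# n-bead single-chain topology, one BB bead per residue
rod_topology <- function(n, first_res = 1, chain = "A", radius = 0.23) {
  bead_topology(seq_len(n), "BB", seq(first_res, length.out = n),
                chain_id = chain, bead_radius = radius)
}

# two-chain topology with identical numbering on both chains
pair_topology <- function(n, first_res = 1, radius = 0.23) {
  bead_topology(seq_len(2 * n), "BB",
                rep(seq(first_res, length.out = n), 2),
                chain_id = rep(c("A", "B"), each = n),
                bead_radius = radius)
}

# beads exactly on a line through `origin` along `direction`
rod_coords <- function(n, direction = c(0, 0, 1), rise = 0.15,
                       origin = c(5, 5, 5)) {
  u <- direction / sqrt(sum(direction^2))
  t_ax <- (seq_len(n) - (n + 1) / 2) * rise
  sweep(outer(t_ax, u), 2, origin, "+")
}

rot3 <- function(axis, angle_deg) tmdimer:::rotation_about(axis, angle_deg)

# quaternion -> rotation matrix
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# brute-force RMSD minimization over rotations: quaternion grid search
# followed by Nelder-Mead refinement; independent of the SVD route
quat_rmsd_oracle <- function(P, Q, n_grid = 800) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  score <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((Qc %*% t(R) - Pc)^2)))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(1234)
  grid <- matrix(rnorm(4 * n_grid), ncol = 4)
  vals <- apply(grid, 1, score)
  best <- grid[which.min(vals), ]
  opt <- stats::optim(best, score, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 20000))
  opt$value
}

# explicit-loop reference implementation of the neighbor-counting
# clustering iteration (no vectorization; written independently)
daura_oracle <- function(m, cutoff) {
  n <- nrow(m)
  assigned <- rep(FALSE, n)
  labels <- rep(NA_integer_, n)
  centers <- integer(0)
  k <- 0L
  tied <- FALSE
  while (any(!assigned)) {
    best_cnt <- -1L; best_i <- NA_integer_; n_best <- 0L
    for (i in seq_len(n)) {
      if (assigned[i]) next
      cnt <- 0L
      for (j in seq_len(n)) {
        if (!assigned[j] && m[i, j] <= cutoff) cnt <- cnt + 1L
      }
      if (cnt > best_cnt) { best_cnt <- cnt; best_i <- i; n_best <- 1L }
      else if (cnt == best_cnt) n_best <- n_best + 1L
    }
    if (n_best > 1L) tied <- TRUE
    k <- k + 1L
    for (j in seq_len(n)) {
      if (!assigned[j] && m[best_i, j] <= cutoff) {
        labels[j] <- k
        assigned[j] <- TRUE
      }
    }
    centers[k] <- best_i
  }
  list(labels = labels, centers = centers, tied = tied)
}

# partition as a canonical list of member sets (order-independent)
partition_of <- function(labels) {
  grp <- split(seq_along(labels), labels)
  grp <- lapply(grp, sort)
  grp[order(vapply(grp, min, 1L))]
}

# random symmetric RMSD-like matrix
random_rmsd_matrix <- function(n, scale = 1) {
  m <- matrix(stats::runif(n * n, 0, 2 * scale), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
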