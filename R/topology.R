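#' Bead topology of a two-helix CG system
#'
#' A static description of the beads in the system: index, bead name
#' (backbone beads are named \code{"BB"}), residue number and name, chain
#' assignment and bead radius. Stored as a data frame with class
#' \code{bead_topology}.
#'
#' @param bead_index integer bead ids (unique).
#' @param bead_name character bead names; backbone beads must be "BB".
#' @param residue_number integer residue numbers (non-decreasing within a
#'   chain; receptor numbering, e.g. IR 940-988).
#' @param residue_name 3-letter residue codes (recycled if length 1).
#' @param chain_id chain labels, one of "A"/"B" (recycled if length 1).
#' @param bead_radius bead radii in nm (> 0; recycled if length 1).
#' @return a \code{bead_topology} data frame.
#' @export
bead_topology <- function(bead_index, bead_name, residue_number,
                          residue_name = "ALA", chain_id = "A",
                          bead_radius = 0.23) {
  n <- length(bead_index)
  top <- data.frame(
    bead_index = as.integer(bead_index),
    bead_name = as.character(bead_name),
    residue_number = as.integer(residue_number),
    residue_name = rep_len(as.character(residue_name), n),
    chain_id = rep_len(as.character(chain_id), n),
    bead_radius = rep_len(as.numeric(bead_radius), n),
    stringsAsFactors = FALSE
  )
  class(top) <- c("bead_topology", "data.frame")
  validate_topology(top)
  top
}

validate_topology <- function(top) {
  if (anyDuplicated(top$bead_index))
    stop("bead_index values must be unique")
  if (any(top$bead_radius <= 0))
    stop("all bead radii must be > 0")
  if (!all(top$chain_id %in% c("A", "B")))
    stop("chain_id must be 'A' or 'B'")
  for (ch in unique(top$chain_id)) {
    rn <- top$residue_number[top$chain_id == ch]
    if (is.unsorted(rn))
      stop("residue_number must be non-decreasing within chain ", ch)
    bb <- top$bead_name[top$chain_id == ch]
    res_with_bb <- unique(top$residue_number[top$chain_id == ch & bb == "BB"])
    if (!all(unique(rn) %in% res_with_bb))
      stop("every residue of chain ", ch, " needs at least one BB bead")
  }
  invisible(top)
}

#' @export
print.bead_topology <- function(x, ...) {
  cat(sprintf("Bead topology: %d beads, chains %s\n", nrow(x),
              paste(unique(x$chain_id), collapse = "+")))
  for (ch in unique(x$chain_id)) {
    rn <- range(x$residue_number[x$chain_id == ch])
    cat(sprintf("  chain %s: residues %d-%d (%d beads)\n", ch, rn[1], rn[2],
                sum(x$chain_id == ch)))
  }
  invisible(x)
}

#' Row indices of beads selected by chain / residue span / bead name
#'
#' @param topology a \code{bead_topology}.
#' @param chain optional chain id ("A" or "B").
#' @param span optional inclusive residue range \code{c(first, last)}.
#' @param bead optional bead-name filter (e.g. "BB"); NULL keeps all beads.
#' @return integer vector of row indices into the topology.
#' @export
select_beads <- function(topology, chain = NULL, span = NULL, bead = NULL) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(chain)) keep <- keep & topology$chain_id == chain
  if (!is.null(span)) {
    keep <- keep & topology$residue_number >= span[1] &
      topology$residue_number <= span[2]
  }
  if (!is.null(bead)) keep <- keep & topology$bead_name == bead
  which(keep)
}

#' A single trajectory frame
#'
#' @param time frame time in ps.
#' @param coords numeric matrix (n_beads x 3) of coordinates in nm.
#' @param box orthorhombic box lengths \code{c(Lx, Ly, Lz)} in nm.
#' @return an object of class \code{md_frame}.
#' @export
md_frame <- function(time, coords, box) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  if (length(box) != 3 || any(box <= 0))
    stop("box must be three positive orthorhombic lengths (nm)")
  structure(list(time = as.numeric(time), coords = coords,
                 box = as.numeric(box)),
            class = "md_frame")
}

#' An in-memory trajectory
#'
#' Frames are stored as a dense array for efficiency; use
#' \code{\link{get_frame}} to extract a single \code{md_frame}.
#'
#' @param topology a \code{bead_topology}.
#' @param times frame times in ps, strictly increasing.
#' @param coords array (n_frames x n_beads x 3), nm.
#' @param box matrix (n_frames x 3) of box lengths in nm, or a length-3
#'   vector reused for all frames.
#' @param metadata free-form provenance list (source file, seed,
#'   generator parameters).
#' @return an object of class \code{md_trajectory}.
#' @export
md_trajectory <- function(topology, times, coords, box, metadata = list()) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be an n_frames x n_beads x 3 array")
  if (dim(coords)[1] != length(times))
    stop("coords first dimension must match the number of times")
  if (dim(coords)[2] != nrow(topology))
    stop("bead count mismatch: coords have ", dim(coords)[2],
         " beads but topology has ", nrow(topology))
  if (is.null(dim(box))) box <- matrix(box, nrow = length(times), ncol = 3,
                                       byrow = TRUE)
  structure(list(topology = topology, times = times, coords = coords,
                 box = box, metadata = metadata),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d beads, t = %g..%g ps\n",
              n_frames(x), nrow(x$topology), min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory an \code{md_trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$times)

#' Extract one frame from a trajectory
#' @param trajectory an \code{md_trajectory}.
#' @param i frame index (1-based).
#' @return an \code{md_frame}.
#' @export
get_frame <- function(trajectory, i) {
  if (i < 1 || i > n_frames(trajectory)) stop("frame index out of range")
  md_frame(trajectory$times[i],
           trajectory$coords[i, , , drop = TRUE],
           trajectory$box[i, ])
}

#' Subset a trajectory by frame indices
#' @param trajectory an \code{md_trajectory}.
#' @param idx integer frame indices, strictly increasing.
#' @return an \code{md_trajectory} restricted to those frames.
#' @export
subset_frames <- function(trajectory, idx) {
  md_trajectory(trajectory$topology, trajectory$times[idx],
                trajectory$coords[idx, , , drop = FALSE],
                trajectory$box[idx, , drop = FALSE],
                trajectory$metadata)
}

#' Receptor analysis presets
#'
#' Residue spans and kink pivots used throughout the analysis, loaded from
#' the preset data file shipped with the package. The insulin receptor
#' (IR) TMD construct spans residues 940-988; its inter-helical distance
#' is measured over residues 953-979 and its tilt over 957-979, with the
#' helix kink pivot at G960/P961. The IGF1R construct spans 919-967 with
#' both measurement spans at 937-959 and the kink pivot at P941.
#'
#' @param receptor "IR" or "IGF1R".
#' @return list with elements \code{residues}, \code{dhh_span},
#'   \code{tilt_span}, \code{membrane_span}, \code{kink_pivot},
#'   \code{orientations} (starting-orientation table) and
#'   \code{production_us} (configured production length per system).
#' @export
tmd_preset <- function(receptor = c("IR", "IGF1R")) {
  receptor <- match.arg(receptor)
  path <- system.file("extdata", "receptor_presets.yaml", package = "tmdimer")
  if (path == "") stop("preset file not found; is tmdimer installed?")
  presets <- yaml::read_yaml(path)
  p <- presets[[receptor]]
  p$receptor <- receptor
  p$orientations <- presets$orientations
  p$production_us <- presets$production_us_per_system
  p$system_size <- presets$system_sizes[[receptor]]
  p
}

#' Build the bead topology of a two-helix homodimer system
#'
#' One backbone ("BB") bead per residue on each of two chains, numbered
#' with the receptor preset's residue range on both chains (chain B
#' restarts the numbering, as in a homodimer).
#'
#' @param receptor "IR" or "IGF1R".
#' @param bead_radius bead radius in nm (default 0.23, the standard CG
#'   bead radius).
#' @return a \code{bead_topology} with 2 x 49 beads.
#' @export
two_helix_topology <- function(receptor = c("IR", "IGF1R"),
                               bead_radius = 0.23) {
  receptor <- match.arg(receptor)
  p <- tmd_preset(receptor)
  res <- seq(p$residues$first, p$residues$last)
  n <- length(res)
  bead_topology(
    bead_index = seq_len(2 * n),
    bead_name = "BB",
    residue_number = c(res, res),
    residue_name = "ALA",
    chain_id = rep(c("A", "B"), each = n),
    bead_radius = bead_radius
  )
}
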