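#' Read a trajectory (DCD or plain-text fallback)
#'
#' Returns all frames in file order with coordinates in nm (DCD stores
#' Angstroms on disk and is converted; the text format is already nm).
#' The plain-text fallback format is documented in the package README:
#' '#'-prefixed comments, then per frame one line
#' \code{F <time_ps> <Lx> <Ly> <Lz>} followed by one \code{x y z} line
#' per bead.
#'
#' @param path trajectory file.
#' @param topology the \code{bead_topology} the file must match.
#' @param format "auto" (by extension), "dcd" or "tsv".
#' @return an \code{md_trajectory}.
#' @export
read_trajectory <- function(path, topology, format = c("auto", "dcd", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path, c("dcd", "tsv", "trj"))
  if (format == "trj") format <- "tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  traj <- switch(format,
                 dcd = read_dcd_file(path),
                 tsv = read_trj_tsv(path),
                 stop("unsupported trajectory format: ", format))
  if (dim(traj$coords)[2] != nrow(topology))
    stop("bead count mismatch: file has ", dim(traj$coords)[2],
         " beads, topology has ", nrow(topology))
  md_trajectory(topology, traj$times, traj$coords, traj$box,
                metadata = list(source = path, format = format))
}

#' Write a trajectory (DCD or plain-text fallback)
#'
#' DCD requires uniformly spaced frame times (the format stores a single
#' time step); use the text format for irregular spacing.
#'
#' @param trajectory an \code{md_trajectory}.
#' @param path output file.
#' @param format "auto" (by extension), "dcd" or "tsv".
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(trajectory, path,
                             format = c("auto", "dcd", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path, c("dcd", "tsv", "trj"))
  if (format == "trj") format <- "tsv"
  switch(format,
         dcd = write_dcd_file(trajectory, path),
         tsv = write_trj_tsv(trajectory, path),
         stop("unsupported trajectory format: ", format))
  invisible(path)
}

partial_read_error <- function(path, frames_recovered, detail) {
  stop(structure(class = c("tmdimer_partial_read", "error", "condition"),
                 list(message = sprintf(
                   "partial read of '%s': %s (%d complete frame%s recovered)",
                   path, detail, frames_recovered,
                   if (frames_recovered == 1) "" else "s"),
                   call = NULL, frames_recovered = frames_recovered)))
}

# ---- DCD (CHARMM-style binary, Angstrom on disk) -------------------------

write_dcd_file <- function(trajectory, path) {
  nf <- n_frames(trajectory)
  if (nf > 1) {
    dts <- diff(trajectory$times)
    if (max(abs(dts - dts[1])) > 1e-6 * max(dts[1], 1))
      stop("DCD requires uniform frame spacing; use the text format")
    delta <- dts[1]
  } else delta <- 1
  istart <- round(trajectory$times[1] / delta)
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(raw_payload) {
    writeBin(as.integer(length(raw_payload)), con, size = 4)
    writeBin(raw_payload, con)
    writeBin(as.integer(length(raw_payload)), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- as.integer(nf); icntrl[2] <- as.integer(istart)
  icntrl[3] <- 1L; icntrl[4] <- as.integer(nf)
  # DCD stores the time step as a float in an integer header slot
  icntrl[10] <- readBin(writeBin(as.numeric(delta), raw(), size = 4),
                        "integer", size = 4)
  icntrl[11] <- 1L  # unit-cell records present
  icntrl[20] <- 24L # CHARMM version flag
  hdr <- c(charToRaw("CORD"), writeBin(as.integer(icntrl), raw(), size = 4))
  rec(hdr)
  title <- sprintf("%-80s", "written by tmdimer")
  rec(c(writeBin(1L, raw(), size = 4), charToRaw(title)))
  rec(writeBin(as.integer(nrow(trajectory$topology)), raw(), size = 4))
  for (i in seq_len(nf)) {
    bx <- trajectory$box[i, ] * 10
    cell <- c(bx[1], 0, bx[2], 0, 0, bx[3])
    rec(writeBin(as.numeric(cell), raw(), size = 8))
    xyz <- trajectory$coords[i, , ] * 10
    rec(writeBin(as.numeric(xyz[, 1]), raw(), size = 4))
    rec(writeBin(as.numeric(xyz[, 2]), raw(), size = 4))
    rec(writeBin(as.numeric(xyz[, 3]), raw(), size = 4))
  }
}

read_dcd_file <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  read_rec <- function() {
    len <- readBin(con, "integer", n = 1, size = 4)
    if (length(len) == 0) return(NULL)
    payload <- readBin(con, "raw", n = len)
    tail_len <- readBin(con, "integer", n = 1, size = 4)
    if (length(payload) < len || length(tail_len) == 0 || tail_len != len)
      return(NA)
    payload
  }
  hdr <- read_rec()
  if (is.null(hdr) || (length(hdr) == 1 && is.na(hdr)) || length(hdr) < 84 ||
      rawToChar(hdr[1:4]) != "CORD")
    partial_read_error(path, 0L, "missing or malformed DCD header")
  icntrl <- readBin(hdr[5:84], "integer", n = 20, size = 4)
  delta <- readBin(writeBin(icntrl[10], raw(), size = 4), "numeric", size = 4)
  istart <- icntrl[2]; nsavc <- max(icntrl[3], 1L)
  has_cell <- icntrl[11] != 0
  title <- read_rec()
  natom_rec <- read_rec()
  if (is.null(natom_rec) || (length(natom_rec) == 1 && is.na(natom_rec)))
    partial_read_error(path, 0L, "truncated before atom-count record")
  natom <- readBin(natom_rec, "integer", size = 4)
  frames <- list(); boxes <- list()
  repeat {
    box <- c(0, 0, 0)
    if (has_cell) {
      cr <- read_rec()
      if (is.null(cr)) break
      if (length(cr) == 1 && is.na(cr))
        partial_read_error(path, length(frames), "truncated unit-cell record")
      cell <- readBin(cr, "numeric", n = 6, size = 8)
      box <- cell[c(1, 3, 6)] / 10
    }
    xr <- read_rec(); yr <- read_rec(); zr <- read_rec()
    if (is.null(xr) && !has_cell) break
    bad <- function(r) is.null(r) || (length(r) == 1 && is.na(r)) ||
      length(r) != 4 * natom
    if (bad(xr) || bad(yr) || bad(zr))
      partial_read_error(path, length(frames), "truncated coordinate record")
    frames[[length(frames) + 1]] <- cbind(
      readBin(xr, "numeric", n = natom, size = 4),
      readBin(yr, "numeric", n = natom, size = 4),
      readBin(zr, "numeric", n = natom, size = 4)) / 10
    boxes[[length(frames)]] <- box
  }
  nf <- length(frames)
  if (nf == 0) partial_read_error(path, 0L, "no frames")
  coords <- array(0, dim = c(nf, natom, 3))
  for (i in seq_len(nf)) coords[i, , ] <- frames[[i]]
  times <- (istart + (seq_len(nf) - 1) * nsavc) * delta
  list(times = times, coords = coords, box = do.call(rbind, boxes))
}

# ---- plain-text fallback (nm / ps) ---------------------------------------

write_trj_tsv <- function(trajectory, path) {
  nf <- n_frames(trajectory)
  nb <- nrow(trajectory$topology)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# tmdimer trajectory text format v1",
               sprintf("# natoms: %d", nb),
               "# per frame: 'F time_ps Lx Ly Lz' then one 'x y z' (nm) line per bead"),
             con)
  for (i in seq_len(nf)) {
    writeLines(sprintf("F %.10g %.10g %.10g %.10g", trajectory$times[i],
                       trajectory$box[i, 1], trajectory$box[i, 2],
                       trajectory$box[i, 3]), con)
    m <- trajectory$coords[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3)
    writeLines(sprintf("%.9f %.9f %.9f", m[, 1], m[, 2], m[, 3]), con)
  }
}

read_trj_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) partial_read_error(path, 0L, "no frames")
  fpos <- grep("^F\\b", lines)
  if (!length(fpos)) partial_read_error(path, 0L, "no frame headers")
  nb <- if (length(fpos) > 1) fpos[2] - fpos[1] - 1 else length(lines) - 1
  times <- numeric(0); boxes <- list(); frames <- list()
  for (k in seq_along(fpos)) {
    hdr <- as.numeric(strsplit(trimws(lines[fpos[k]]), "\\s+")[[1]][-1])
    lo <- fpos[k] + 1
    hi <- fpos[k] + nb
    if (hi > length(lines) || (k < length(fpos) && hi >= fpos[k + 1]))
      partial_read_error(path, length(frames), "truncated frame block")
    m <- matrix(as.numeric(unlist(strsplit(trimws(lines[lo:hi]), "\\s+"))),
                ncol = 3, byrow = TRUE)
    if (anyNA(m) || anyNA(hdr) || length(hdr) != 4)
      partial_read_error(path, length(frames), "unparseable frame block")
    times <- c(times, hdr[1])
    boxes[[k]] <- hdr[2:4]
    frames[[k]] <- m
  }
  coords <- array(0, dim = c(length(frames), nb, 3))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  list(times = times, coords = coords, box = do.call(rbind, boxes))
}

# ---- metric tables -------------------------------------------------------

#' Write a per-frame metrics table as commented TSV
#'
#' Tab-separated values preceded by '#' header lines naming the columns
#' and their units; parseable back with \code{\link{read_metrics_table}}.
#'
#' @param rows a data frame (one row per frame).
#' @param path output path.
#' @param units optional named character vector of unit strings per column.
#' @return \code{path}, invisibly.
#' @export
write_metrics_table <- function(rows, path, units = NULL) {
  rows <- as.data.frame(rows)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines("# tmdimer metrics table", con)
  if (!is.null(units))
    writeLines(paste0("# units: ", paste(names(units), units, sep = "=",
                                         collapse = " ")), con)
  writeLines(paste0("# columns: ", paste(names(rows), collapse = "\t")), con)
  if (nrow(rows))
    utils::write.table(rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a metrics table written by \code{write_metrics_table}
#'
#' @param path file path.
#' @return a data frame with the original column names.
#' @export
read_metrics_table <- function(path) {
  hdr <- grep("^# columns:", readLines(path, n = 50), value = TRUE)
  if (!length(hdr)) stop("not a tmdimer metrics table: ", path)
  cols <- strsplit(sub("^# columns:\\s*", "", hdr[1]), "\t")[[1]]
  has_data <- any(!grepl("^\\s*#|^\\s*$", readLines(path)))
  if (!has_data) {
    df <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(df) <- cols
    return(df)
  }
  utils::read.table(path, sep = "\t", comment.char = "#",
                    col.names = cols, stringsAsFactors = FALSE)
}
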