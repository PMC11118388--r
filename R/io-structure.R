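#' Read a structure file (GRO or PDB)
#'
#' Parses a single-model structure into a \code{bead_topology} and an
#' \code{md_frame}. GRO coordinates are read as nm; PDB coordinates (in
#' Angstroms on disk) are converted to nm. GRO carries no chain records,
#' so chains are inferred from residue numbering: a drop in residue number
#' starts chain B. Bead radii are not stored in either format and are
#' supplied via \code{bead_radius}.
#'
#' @param path file path.
#' @param format "auto" (by extension), "gro" or "pdb".
#' @param bead_radius radius (nm) assigned to every bead, or a vector with
#'   one radius per bead.
#' @return list with elements \code{topology} (\code{bead_topology}) and
#'   \code{frame} (\code{md_frame}).
#' @export
read_structure <- function(path, format = c("auto", "gro", "pdb"),
                           bead_radius = 0.23) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path, c("gro", "pdb"))
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         gro = read_gro(path, bead_radius),
         pdb = read_pdb_structure(path, bead_radius),
         stop("unsupported structure format: ", format))
}

#' Write a structure file (GRO or PDB)
#'
#' Inverse of \code{\link{read_structure}} up to format precision
#' (GRO: 1e-3 nm; PDB: 1e-3 Angstrom). PDB output includes a CRYST1
#' record holding the orthorhombic box.
#'
#' @param topology a \code{bead_topology}.
#' @param frame an \code{md_frame}.
#' @param path output file path.
#' @param format "auto" (by extension), "gro" or "pdb".
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(topology, frame, path,
                            format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path, c("gro", "pdb"))
  if (nrow(topology) != nrow(frame$coords))
    stop("topology and frame bead counts differ")
  switch(format,
         gro = write_gro(topology, frame, path),
         pdb = write_pdb_structure(topology, frame, path),
         stop("unsupported structure format: ", format))
  invisible(path)
}

guess_format <- function(path, allowed) {
  ext <- tolower(tools::file_ext(sub("\\.tsv$", "", path)))
  if (ext == "" || !(ext %in% allowed))
    ext <- tolower(tools::file_ext(path))
  if (!(ext %in% allowed))
    stop("cannot infer format of '", path, "'; expected one of: ",
         paste(allowed, collapse = ", "))
  ext
}

# ---- GRO (fixed-width, GROMACS dialect; lengths in nm) -------------------

read_gro <- function(path, bead_radius) {
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("malformed GRO file (need title, count, atoms, box): ", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms))
    stop("malformed GRO file at line 2: atom count not an integer")
  if (length(lines) < 2 + natoms + 1)
    stop("malformed GRO file: expected ", natoms, " atom lines, file ends at line ",
         length(lines))
  al <- lines[3:(2 + natoms)]
  num <- function(s, from, to) suppressWarnings(as.numeric(substr(s, from, to)))
  resno <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resid <- trimws(substr(al, 6, 10))
  aname <- trimws(substr(al, 11, 15))
  x <- num(al, 21, 28); y <- num(al, 29, 36); z <- num(al, 37, 44)
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed GRO atom record at line ", 2 + bad[1])
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[2 + natoms + 1]),
                                               "\\s+")[[1]]))
  if (length(boxv) > 3 && any(boxv[4:length(boxv)] != 0))
    stop("triclinic box not supported (off-diagonal box elements at line ",
         2 + natoms + 1, ")")
  if (length(boxv) < 3 || any(is.na(boxv[1:3])))
    stop("malformed GRO box line at line ", 2 + natoms + 1)
  chain <- chains_from_resno(resno)
  top <- bead_topology(seq_len(natoms), aname, resno, resid, chain, bead_radius)
  frame <- md_frame(0, cbind(x, y, z), boxv[1:3])
  list(topology = top, frame = frame)
}

# GRO has no chain field: a drop in residue number starts chain B
chains_from_resno <- function(resno) {
  brk <- which(diff(resno) < 0)
  chain <- rep("A", length(resno))
  if (length(brk) >= 1) chain[(brk[1] + 1):length(resno)] <- "B"
  chain
}

write_gro <- function(topology, frame, path) {
  n <- nrow(topology)
  lines <- c(
    "two-helix CG system written by tmdimer",
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            topology$residue_number %% 100000L,
            substr(topology$residue_name, 1, 5),
            substr(topology$bead_name, 1, 5),
            topology$bead_index %% 100000L,
            frame$coords[, 1], frame$coords[, 2], frame$coords[, 3]),
    sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3])
  )
  writeLines(lines, path)
}

# ---- PDB (via bio3d; Angstrom on disk) -----------------------------------

read_pdb_structure <- function(path, bead_radius) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("malformed PDB file '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  chain <- at$chain
  if (all(is.na(chain)) || all(chain == ""))
    chain <- chains_from_resno(at$resno)
  top <- bead_topology(seq_len(nrow(at)), at$elety, at$resno, at$resid,
                       chain, bead_radius)
  coords <- cbind(at$x, at$y, at$z) / 10  # Angstrom -> nm
  box <- pdb_cryst1_box(path)
  if (is.null(box)) {
    rng <- apply(coords, 2, function(v) diff(range(v)))
    box <- pmax(rng + 2, 1)
    warning("no CRYST1 record in ", path, "; using bounding box + 2 nm")
  }
  list(topology = top, frame = md_frame(0, coords, box))
}

pdb_cryst1_box <- function(path) {
  ln <- grep("^CRYST1", readLines(path, n = 500), value = TRUE)
  if (!length(ln)) return(NULL)
  a <- as.numeric(substr(ln[1], 7, 15))
  b <- as.numeric(substr(ln[1], 16, 24))
  c_ <- as.numeric(substr(ln[1], 25, 33))
  ang <- c(as.numeric(substr(ln[1], 34, 40)),
           as.numeric(substr(ln[1], 41, 47)),
           as.numeric(substr(ln[1], 48, 54)))
  if (any(!is.na(ang) & abs(ang - 90) > 1e-6))
    stop("triclinic box in CRYST1 record not supported")
  c(a, b, c_) / 10
}

write_pdb_structure <- function(topology, frame, path) {
  xyz <- as.vector(t(frame$coords * 10))  # nm -> Angstrom
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = topology$residue_number,
                   resid = topology$residue_name,
                   eleno = topology$bead_index,
                   elety = topology$bead_name,
                   chain = topology$chain_id)
  body <- readLines(path)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   frame$box[1] * 10, frame$box[2] * 10, frame$box[3] * 10,
                   90, 90, 90)
  writeLines(c(cryst, body), path)
}
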