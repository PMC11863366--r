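#' Load a molecular system from topology (and optional trajectory) files
#'
#' Reads GRO, PDB or XYZ files into an in-memory system. The topology file
#' provides atom metadata and the first frame; an optional trajectory file
#' (same supported formats, multi-frame) replaces or extends the coordinate
#' frames. All coordinates are stored in Angstrom; GRO input (natively nm)
#' is converted on read. Only orthorhombic boxes are supported; triclinic
#' input raises an error.
#'
#' @param topology path to a GRO, PDB or XYZ file.
#' @param trajectory optional path to a (multi-frame) coordinate file. Its
#'   atom count must match the topology in every frame.
#' @param box optional length-3 numeric (Angstrom) used for XYZ files whose
#'   comment line carries no `Lattice="..."` entry.
#' @return an object of class `md_system`: a list with `atoms` (data frame
#'   with columns `id`, `name`, `element`, `resid`, `resname`), `frames`
#'   (list of frames, each with `xyz` (n x 3 matrix, Angstrom), `box`
#'   (length-3, Angstrom) and `index`), and the source paths.
#' @examples
#' sys <- make_fixture("sphere", radius = 10, spacing = 3, box = c(30, 30, 30))
#' f <- tempfile(fileext = ".gro")
#' write_trajectory(sys, f)
#' sys2 <- load_system(f)
#' n_frames(sys2)
#' @export
load_system <- function(topology, trajectory = NULL, box = NULL) {
  if (!file.exists(topology))
    stop_fmt("cannot read topology file: '%s'", topology)
  top <- read_coords(topology, box = box)
  sys <- structure(
    list(atoms = top$atoms, frames = top$frames,
         topology = topology, trajectory = trajectory),
    class = "md_system")
  if (!is.null(trajectory)) {
    if (!file.exists(trajectory))
      stop_fmt("cannot read trajectory file: '%s'", trajectory)
    trj <- read_coords(trajectory, box = box)
    nt <- nrow(top$atoms)
    for (i in seq_along(trj$frames)) {
      if (nrow(trj$frames[[i]]$xyz) != nt)
        stop_fmt(paste0("atom count mismatch between topology (%d) and ",
                        "trajectory frame %d (%d)"),
                 nt, i - 1L, nrow(trj$frames[[i]]$xyz))
    }
    sys$frames <- trj$frames
  }
  for (i in seq_along(sys$frames)) {
    sys$frames[[i]]$index <- i - 1L
    if (any(!is.finite(sys$frames[[i]]$xyz)))
      stop_fmt("non-finite coordinates in frame %d", i - 1L)
    if (any(sys$frames[[i]]$box <= 0))
      stop_fmt("non-positive box lengths in frame %d", i - 1L)
  }
  sys
}

#' Number of frames in a system
#' @param system an `md_system`.
#' @return integer frame count.
#' @export
n_frames <- function(system) length(system$frames)

#' @export
print.md_system <- function(x, ...) {
  cat(sprintf("<md_system> %d atoms, %d residues, %d frame(s)\n",
              nrow(x$atoms), length(unique(x$atoms$resid)),
              length(x$frames)))
  b <- x$frames[[1]]$box
  cat(sprintf("  box: %.2f x %.2f x %.2f Angstrom\n", b[1], b[2], b[3]))
  invisible(x)
}

#' Iterate over a frame range
#'
#' Returns the frames `start, start + skip, ...` strictly below `end`.
#' Frames are indexed from zero, following the convention of MD analysis
#' tooling, and the range is half-open.
#'
#' @param system an `md_system`.
#' @param start first frame index (0-based). Default 0.
#' @param end one past the last frame index; `NULL` means the frame count.
#' @param skip stride between frames, at least 1.
#' @return list of frame objects, possibly empty.
#' @export
iter_frames <- function(system, start = 0L, end = NULL, skip = 1L) {
  nf <- length(system$frames)
  end <- end %||% nf
  if (skip < 1L) stop_fmt("skip must be >= 1 (got %s)", skip)
  if (start < 0L || end > nf || start > end)
    stop_fmt("frame range [%s, %s) out of bounds for %d frames",
             start, end, nf)
  if (start >= end) return(list())
  idx <- seq.int(start, end - 1L, by = skip)
  system$frames[idx + 1L]
}

#' Write a system to a trajectory file
#'
#' The output format is inferred from the file extension (`.gro`, `.pdb` or
#' `.xyz`). GRO output is written in nm at the format's fixed precision;
#' re-loading reproduces coordinates to about 1e-2 Angstrom for GRO and XYZ,
#' and 1e-3 Angstrom for PDB.
#'
#' @param system an `md_system`.
#' @param path output path.
#' @param frames optional 0-based frame indices to write (default: all).
#' @return the path, invisibly.
#' @export
write_trajectory <- function(system, path, frames = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("gro", "pdb", "xyz"))
    stop_fmt("unsupported trajectory extension '.%s' (use gro, pdb or xyz)",
             ext)
  fr <- if (is.null(frames)) system$frames else {
    if (any(frames < 0L | frames >= length(system$frames)))
      stop_fmt("frame subset out of range")
    system$frames[frames + 1L]
  }
  lines <- switch(ext,
    gro = format_gro(system$atoms, fr),
    pdb = format_pdb(system$atoms, fr),
    xyz = format_xyz(system$atoms, fr))
  writeLines(lines, path)
  invisible(path)
}

# --- readers -----------------------------------------------------------------

read_coords <- function(path, box = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    gro = read_gro(path),
    pdb = read_pdb(path),
    xyz = read_xyz(path, box = box),
    stop_fmt("unsupported file format '.%s' for '%s' (use gro, pdb or xyz)",
             ext, path))
}

guess_element <- function(name) {
  # leading letters of the atom name, digits stripped; one- or two-letter
  el <- sub("^[0-9]*", "", name)
  el <- sub("[^A-Za-z].*$", "", el)
  two <- c("Cl", "Br", "Na", "Mg", "Ca", "Fe", "Zn", "Se", "Si", "Li", "Al")
  first2 <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
  ifelse(first2 %in% two, first2, toupper(substr(el, 1, 1)))
}

atoms_frame <- function(id, name, resid, resname, element = NULL) {
  data.frame(id = as.integer(id), name = name,
             element = element %||% guess_element(name),
             resid = as.integer(resid), resname = resname,
             stringsAsFactors = FALSE)
}

read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) ) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat))
      stop_fmt("malformed GRO atom-count line %d in '%s'", i + 1L, path)
    if (i + 1L + nat + 1L > length(lines))
      stop_fmt("truncated GRO frame starting at line %d in '%s'", i, path)
    al <- lines[(i + 2L):(i + 1L + nat)]
    x <- as.numeric(substr(al, 21, 28)) * 10
    y <- as.numeric(substr(al, 29, 36)) * 10
    z <- as.numeric(substr(al, 37, 44)) * 10
    if (any(is.na(x) | is.na(y) | is.na(z)))
      stop_fmt("malformed GRO coordinates in frame %d of '%s'",
               length(frames), path)
    bl <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]])
    if (length(bl) < 3) stop_fmt("malformed GRO box line in '%s'", path)
    if (length(bl) > 3 && any(abs(bl[4:length(bl)]) > 1e-9))
      stop_fmt("triclinic boxes are not supported ('%s')", path)
    if (is.null(atoms)) {
      atoms <- atoms_frame(
        id = seq_len(nat),
        name = trimws(substr(al, 11, 15)),
        resid = as.integer(substr(al, 1, 5)),
        resname = trimws(substr(al, 6, 10)))
    }
    frames[[length(frames) + 1L]] <- list(
      xyz = cbind(x, y, z, deparse.level = 0),
      box = bl[1:3] * 10, index = length(frames))
    i <- i + nat + 3L
  }
  if (length(frames) == 0L) stop_fmt("no frames found in '%s'", path)
  list(atoms = atoms, frames = frames)
}

read_pdb <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  box <- NULL
  cr <- which(rec == "CRYST1")
  if (length(cr)) {
    l <- lines[cr[1]]
    box <- as.numeric(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33)))
    ang <- as.numeric(c(substr(l, 34, 40), substr(l, 41, 47), substr(l, 48, 54)))
    if (any(abs(ang - 90) > 1e-6))
      stop_fmt("triclinic boxes are not supported ('%s')", path)
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  ends <- which(rec == "ENDMDL")
  # frame boundaries: split atom records at ENDMDL markers (or single frame)
  frame_of <- findInterval(which(is_atom), c(0, ends)) + 1L
  ai <- which(is_atom)
  if (!length(ai)) stop_fmt("no ATOM/HETATM records in '%s'", path)
  frames <- list()
  atoms <- NULL
  for (f in unique(frame_of)) {
    al <- lines[ai[frame_of == f]]
    x <- as.numeric(substr(al, 31, 38))
    y <- as.numeric(substr(al, 39, 46))
    z <- as.numeric(substr(al, 47, 54))
    if (any(is.na(x) | is.na(y) | is.na(z)))
      stop_fmt("malformed PDB coordinates in frame %d of '%s'",
               length(frames), path)
    if (is.null(atoms)) {
      el <- trimws(substr(al, 77, 78))
      name <- trimws(substr(al, 13, 16))
      atoms <- atoms_frame(
        id = seq_along(al), name = name,
        resid = as.integer(substr(al, 23, 26)),
        resname = trimws(substr(al, 18, 21)),
        element = ifelse(nzchar(el), el, guess_element(name)))
    } else if (length(al) != nrow(atoms)) {
      stop_fmt("atom count mismatch in frame %d of '%s' (%d vs %d)",
               length(frames), path, length(al), nrow(atoms))
    }
    frames[[length(frames) + 1L]] <- list(
      xyz = cbind(x, y, z, deparse.level = 0),
      box = box %||% c(NA_real_, NA_real_, NA_real_),
      index = length(frames))
  }
  if (is.null(box))
    stop_fmt("no CRYST1 box record in '%s'", path)
  list(atoms = atoms, frames = frames)
}

xyz_lattice_box <- function(comment) {
  m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
  if (!length(m)) return(NULL)
  v <- as.numeric(strsplit(sub('^Lattice="', "", sub('"$', "", m)),
                           "\\s+")[[1]])
  if (length(v) != 9) return(NULL)
  offdiag <- v[c(2, 3, 4, 6, 7, 8)]
  if (any(abs(offdiag) > 1e-9))
    stop_fmt("triclinic boxes are not supported (XYZ Lattice entry)")
  v[c(1, 5, 9)]
}

read_xyz <- function(path, box = NULL) {
  lines <- readLines(path)
  frames <- list()
  atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat))
      stop_fmt("malformed XYZ atom-count line %d in '%s'", i, path)
    if (i + 1L + nat > length(lines))
      stop_fmt("truncated XYZ frame starting at line %d in '%s'", i, path)
    fbox <- xyz_lattice_box(lines[i + 1L]) %||% box
    if (is.null(fbox))
      stop_fmt(paste0("no box information for '%s': supply `box=` or a ",
                      'Lattice="..." comment'), path)
    al <- strsplit(trimws(lines[(i + 2L):(i + 1L + nat)]), "\\s+")
    bad <- which(lengths(al) < 4)
    if (length(bad))
      stop_fmt("malformed XYZ atom line %d in '%s'", i + 1L + bad[1], path)
    name <- vapply(al, `[[`, "", 1L)
    xyz <- t(vapply(al, function(v) as.numeric(v[2:4]), numeric(3)))
    if (any(is.na(xyz)))
      stop_fmt("malformed XYZ coordinates in frame %d of '%s'",
               length(frames), path)
    if (is.null(atoms)) {
      atoms <- atoms_frame(id = seq_len(nat), name = name,
                           resid = seq_len(nat), resname = "MOL")
    } else if (nat != nrow(atoms)) {
      stop_fmt("atom count mismatch in frame %d of '%s' (%d vs %d)",
               length(frames), path, nat, nrow(atoms))
    }
    frames[[length(frames) + 1L]] <- list(
      xyz = unname(xyz), box = as.numeric(fbox), index = length(frames))
    i <- i + nat + 2L
  }
  if (length(frames) == 0L) stop_fmt("no frames found in '%s'", path)
  list(atoms = atoms, frames = frames)
}

# --- writers -----------------------------------------------------------------

format_gro <- function(atoms, frames) {
  unlist(lapply(frames, function(fr) {
    body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    atoms$resid %% 100000L, atoms$resname,
                    substr(atoms$name, 1, 5), atoms$id %% 100000L,
                    fr$xyz[, 1] / 10, fr$xyz[, 2] / 10, fr$xyz[, 3] / 10)
    c("written by hullprof", sprintf("%5d", nrow(atoms)), body,
      sprintf("%10.5f%10.5f%10.5f", fr$box[1] / 10, fr$box[2] / 10,
              fr$box[3] / 10))
  }), use.names = FALSE)
}

format_pdb <- function(atoms, frames) {
  multi <- length(frames) > 1
  out <- character(0)
  b <- frames[[1]]$box
  out <- c(out, sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    b[1], b[2], b[3], 90, 90, 90))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (multi) out <- c(out, sprintf("MODEL     %4d", k))
    out <- c(out, sprintf(
      "ATOM  %5d %-4s%-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      atoms$id %% 100000L, substr(atoms$name, 1, 4),
      substr(atoms$resname, 1, 4), atoms$resid %% 10000L,
      fr$xyz[, 1], fr$xyz[, 2], fr$xyz[, 3], atoms$element))
    if (multi) out <- c(out, "ENDMDL")
  }
  c(out, "END")
}

format_xyz <- function(atoms, frames) {
  unlist(lapply(frames, function(fr) {
    c(sprintf("%d", nrow(atoms)),
      sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g" written by hullprof',
              fr$box[1], fr$box[2], fr$box[3]),
      sprintf("%-4s %12.6f %12.6f %12.6f", atoms$name,
              fr$xyz[, 1], fr$xyz[, 2], fr$xyz[, 3]))
  }), use.names = FALSE)
}
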