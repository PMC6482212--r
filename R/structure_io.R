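# Reading and validating the reference structure, the training trajectory and
# the table of precomputed collective-variable values.
#
# Internal unit convention: nanometres everywhere.  PDB and DCD files store
# Angstroms and are converted on read (divided by 10); TRR is natively in nm.

#' Define the scaling box
#'
#' The reference structure must sit in a rectangular box with one corner at
#' the origin and the diagonal corner at \code{(lx, ly, lz)} (in nm).  After
#' superposition every coordinate is divided by the corresponding edge length
#' so the network inputs lie in \[0, 1\].
#'
#' @param lx,ly,lz box edge lengths in nm, strictly positive.
#' @return An object of class \code{box_spec}.
#' @examples
#' box_spec(1, 1, 1)
#' @export
box_spec <- function(lx, ly, lz = ly) {
  l <- c(lx, ly, lz)
  if (length(l) != 3L || !all(is.finite(l)) || any(l <= 0)) {
    stopf("box edge lengths must be three strictly positive finite numbers")
  }
  structure(list(lx = as.numeric(lx), ly = as.numeric(ly), lz = as.numeric(lz)),
            class = "box_spec")
}

#' @export
print.box_spec <- function(x, ...) {
  cat(sprintf("<box_spec> %g x %g x %g nm\n", x$lx, x$ly, x$lz))
  invisible(x)
}

box_lengths <- function(box) c(box$lx, box$ly, box$lz)

#' Load the reference structure
#'
#' Reads a PDB file containing exactly the analysis atoms (every ATOM/HETATM
#' record is used; no element or name filtering is performed) and validates
#' that every atom lies inside the scaling box.  Original atom serial numbers
#' are preserved even when non-contiguous (e.g. 1, 4, 7, ... after deleting
#' hydrogens), because the exported PLUMED file refers to atoms by these
#' serials.
#'
#' @param path path to a PDB file.
#' @param box a \code{\link{box_spec}}; the molecule must fit inside
#'   \code{[0, lx] x [0, ly] x [0, lz]} (nm).
#' @return An object of class \code{reference_structure} with fields
#'   \code{atom_count}, \code{atom_serials}, \code{coords} (N x 3 matrix, nm),
#'   \code{box} and \code{atom} (the PDB atom table kept for template
#'   re-export).
#' @seealso \code{\link{load_trajectory}}, \code{\link{load_cv_table}}
#' @export
load_reference <- function(path, box) {
  if (!inherits(box, "box_spec")) stopf("`box` must be a box_spec")
  if (!file.exists(path)) stopf("reference PDB not found: %s", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stopf("cannot parse PDB file %s: %s", path, conditionMessage(e))
  )
  atom <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  n <- nrow(atom)
  if (n < 1L) stopf("reference PDB %s contains no ATOM/HETATM records", path)
  coords <- cbind(atom$x, atom$y, atom$z) / 10  # Angstrom -> nm
  if (!all(is.finite(coords))) stopf("non-finite coordinates in %s", path)
  ref <- structure(
    list(atom_count = n,
         atom_serials = as.integer(atom$eleno),
         coords = unname(coords),
         box = box,
         atom = atom),
    class = "reference_structure")
  check_in_box(ref$coords, box, serials = ref$atom_serials,
               what = "reference atom")
  ref
}

# Error if any coordinate falls outside [0, l] on any axis (nm), naming the
# offending atom and axis.  `tol` absorbs last-digit rounding of PDB files.
check_in_box <- function(coords, box, serials, what = "atom",
                         frame = NULL, tol = 1e-9) {
  l <- box_lengths(box)
  ax <- c("x", "y", "z")
  for (j in 1:3) {
    bad <- which(coords[, j] < -tol | coords[, j] > l[j] + tol)
    if (length(bad) > 0L) {
      i <- bad[1L]
      where <- if (is.null(frame)) "" else sprintf(" in frame %d", frame)
      stopf(paste0("%s %d%s lies outside the box on axis %s: ",
                   "coordinate %.4f nm not in [0, %.4f] ",
                   "(enlarge the box or re-centre the structure)"),
            what, serials[i], where, ax[j], coords[i, j], l[j])
    }
  }
  invisible(TRUE)
}

#' @export
print.reference_structure <- function(x, ...) {
  cat(sprintf("<reference_structure> %d atoms, box %g x %g x %g nm\n",
              x$atom_count, x$box$lx, x$box$ly, x$box$lz))
  invisible(x)
}

#' Load a training trajectory
#'
#' Reads an ensemble of conformations of exactly the atoms in the reference
#' structure.  The format is sniffed from the file extension: \code{.pdb}
#' (multi-model, split on MODEL/ENDMDL), \code{.dcd} (CHARMM/X-PLOR binary,
#' read through bio3d) or \code{.trr} (GROMACS).  XTC is not supported; convert
#' to TRR or DCD first.  Frames must not contain molecules broken across
#' periodic boundaries; no reconstruction is attempted.
#'
#' @param path path to the trajectory file.
#' @param reference a \code{\link{load_reference}} result; the trajectory must
#'   contain the same number of atoms.
#' @return An object of class \code{trajectory} with fields
#'   \code{frame_count}, \code{coords} (F x N x 3 array, nm) and
#'   \code{source_format}.
#' @export
load_trajectory <- function(path, reference) {
  if (!inherits(reference, "reference_structure")) {
    stopf("`reference` must be a reference_structure")
  }
  if (!file.exists(path)) stopf("trajectory file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  coords <- switch(ext,
    pdb = read_multimodel_pdb(path),
    dcd = read_dcd_nm(path),
    trr = read_trr(path)$coords,
    xtc = stopf(paste0("XTC trajectories are not supported (compressed ",
                       "coordinates); convert to TRR, DCD or multi-model ",
                       "PDB, e.g. `gmx trjconv -f %s -o traj.trr`")
                , basename(path)),
    stopf("unrecognised trajectory format '.%s' for %s (use pdb/dcd/trr)",
          ext, path)
  )
  n <- dim(coords)[2L]
  if (n != reference$atom_count) {
    stopf("trajectory %s has %d atoms but the reference has %d",
          path, n, reference$atom_count)
  }
  if (!all(is.finite(coords))) stopf("non-finite coordinates in %s", path)
  structure(
    list(frame_count = dim(coords)[1L], coords = coords,
         source_format = if (ext == "pdb") "pdb-multimodel" else ext),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms (%s)\n",
              x$frame_count, dim(x$coords)[2L], x$source_format))
  invisible(x)
}

# F x N x 3 array in nm from a multi-model PDB.
read_multimodel_pdb <- function(path) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stopf("cannot parse PDB trajectory %s: %s",
                              path, conditionMessage(e))
  )
  xyz <- pdb$xyz                     # frames x 3N matrix, Angstrom
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  f <- nrow(xyz)
  n <- ncol(xyz) / 3L
  arr <- array(NA_real_, dim = c(f, n, 3L))
  for (k in 1:3) arr[, , k] <- xyz[, seq(k, by = 3L, length.out = n), drop = FALSE]
  arr / 10
}

read_dcd_nm <- function(path) {
  xyz <- tryCatch(
    bio3d::read.dcd(path, verbose = FALSE),
    error = function(e) stopf("cannot read DCD file %s: %s",
                              path, conditionMessage(e))
  )
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  f <- nrow(xyz)
  n <- ncol(xyz) / 3L
  arr <- array(NA_real_, dim = c(f, n, 3L))
  for (k in 1:3) arr[, , k] <- xyz[, seq(k, by = 3L, length.out = n), drop = FALSE]
  arr / 10
}

#' Load a table of precomputed collective-variable values
#'
#' Reads one scalar per trajectory frame from a whitespace-separated text
#' file, in frame order.  Blank lines and lines starting with \code{#} are
#' skipped; any other non-numeric cell in the requested column is an error
#' (there is no header detection).
#'
#' @param path path to the text table.
#' @param column_index 1-based index of the column holding the CV.
#' @param expected_rows number of data rows the table must contain (the
#'   trajectory frame count); pass \code{NULL} to skip the check.
#' @return An object of class \code{cv_series} with fields \code{values},
#'   \code{column_index} and \code{labels} (filled in later by
#'   \code{\link{split_dataset}}).
#' @export
load_cv_table <- function(path, column_index = 1L, expected_rows = NULL) {
  if (!is_count(column_index) || column_index < 1L) {
    stopf("`column_index` must be a positive integer (1-based)")
  }
  if (!file.exists(path)) stopf("CV table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  rowno <- which(keep)
  if (!is.null(expected_rows) && length(lines) != expected_rows) {
    stopf("CV table %s has %d data rows but the trajectory has %d frames",
          path, length(lines), expected_rows)
  }
  values <- numeric(length(lines))
  for (i in seq_along(lines)) {
    cells <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(cells) < column_index) {
      stopf("CV table %s row %d (line %d) has %d columns; column %d requested",
            path, i, rowno[i], length(cells), column_index)
    }
    v <- suppressWarnings(as.numeric(cells[column_index]))
    if (is.na(v)) {
      stopf("CV table %s row %d (line %d): non-numeric value '%s' in column %d",
            path, i, rowno[i], cells[column_index], column_index)
    }
    values[i] <- v
  }
  if (!all(is.finite(values))) stopf("CV table %s contains non-finite values", path)
  structure(list(values = values, column_index = as.integer(column_index),
                 labels = NULL),
            class = "cv_series")
}

#' @export
print.cv_series <- function(x, ...) {
  cat(sprintf("<cv_series> %d values from column %d, range [%g, %g]\n",
              length(x$values), x$column_index,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Check that trajectory, reference and CV series are mutually consistent
#'
#' The pipeline refuses to proceed unless the trajectory matches the reference
#' atom count and the CV series has one value per frame.
#'
#' @param trajectory a \code{trajectory}.
#' @param reference a \code{reference_structure}.
#' @param cv a \code{cv_series}.
#' @return \code{TRUE}, invisibly; errors otherwise.
#' @export
check_consistency <- function(trajectory, reference, cv) {
  if (dim(trajectory$coords)[2L] != reference$atom_count) {
    stopf("trajectory has %d atoms but the reference has %d",
          dim(trajectory$coords)[2L], reference$atom_count)
  }
  if (length(cv$values) != trajectory$frame_count) {
    stopf("CV series has %d values but the trajectory has %d frames",
          length(cv$values), trajectory$frame_count)
  }
  invisible(TRUE)
}

#' Write a structure or trajectory as PDB
#'
#' Single-frame writes produce a plain PDB; multi-frame writes produce a
#' multi-model PDB that \code{\link{load_trajectory}} reads back.  Coordinates
#' are taken in nm and written in Angstrom at PDB precision (1e-3 A).
#'
#' @param coords N x 3 matrix or F x N x 3 array, nm.
#' @param path output path.
#' @param serials atom serial numbers (default 1..N).
#' @return \code{path}, invisibly.
#' @export
write_pdb_nm <- function(coords, path, serials = NULL) {
  if (length(dim(coords)) == 2L) {
    coords <- array(coords, dim = c(1L, dim(coords)))
  }
  f <- dim(coords)[1L]; n <- dim(coords)[2L]
  if (is.null(serials)) serials <- seq_len(n)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in seq_len(f)) {
    if (f > 1L) writeLines(sprintf("MODEL %8d", fr), con)
    writeLines(format_pdb_atoms(matrix(coords[fr, , ], ncol = 3L) * 10,
                                serials), con)
    if (f > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Fixed-width ATOM records (coordinates already in Angstrom).
format_pdb_atoms <- function(xyz, serials, occ = 1, beta = 1,
                             elety = NULL, resid = "UNK", chain = "A",
                             resno = 1L) {
  n <- nrow(xyz)
  if (is.null(elety)) elety <- rep("C", n)
  sprintf("ATOM  %5d %-4s%-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serials,
          substr(sprintf(" %-3s", elety), 1, 4),
          rep(resid, length.out = n), rep(chain, length.out = n),
          rep(resno, length.out = n),
          xyz[, 1], xyz[, 2], xyz[, 3],
          rep(occ, length.out = n), rep(beta, length.out = n))
}
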