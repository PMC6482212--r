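# Minimal binary trajectory I/O: GROMACS TRR (read + write) and CHARMM/X-PLOR
# DCD (write; reading goes through bio3d::read.dcd).  Only the coordinate
# stream is handled -- velocities, forces, virial and pressure blocks are
# never written and are skipped on read.

TRR_MAGIC <- 1993L

#' Write a TRR trajectory
#'
#' Writes single-precision coordinate frames in the GROMACS TRR container
#' (big-endian XDR).  Coordinates are in nm, the container's native unit.
#' A diagonal box is stored with every frame.
#'
#' @param coords F x N x 3 array (or N x 3 matrix for one frame), nm.
#' @param path output path.
#' @param box a \code{\link{box_spec}} stored as the (diagonal) unit cell.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{read_trr}}
#' @export
write_trr <- function(coords, path, box = NULL) {
  if (length(dim(coords)) == 2L) coords <- array(coords, dim = c(1L, dim(coords)))
  f <- dim(coords)[1L]; n <- dim(coords)[2L]
  boxmat <- if (is.null(box)) NULL else diag(box_lengths(box))
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "big")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "big")
  box_size <- if (is.null(boxmat)) 0L else 36L
  for (fr in seq_len(f)) {
    wint(TRR_MAGIC)
    wint(13L); wint(12L)                      # version string, XDR-encoded
    writeBin(charToRaw("GMX_trn_file"), con)
    wint(c(0L, 0L,                            # ir_size, e_size
           box_size,
           0L, 0L, 0L, 0L,                    # vir, pres, top, sym
           3L * n * 4L,                       # x_size
           0L, 0L,                            # v_size, f_size
           n, fr - 1L, 0L))                   # natoms, step, nre
    wflt(c(0, 0))                             # t, lambda
    if (!is.null(boxmat)) wflt(as.vector(t(boxmat)))
    wflt(as.vector(t(coords[fr, , , drop = TRUE])))  # atom-major x,y,z
  }
  invisible(path)
}

#' Read a TRR trajectory
#'
#' Reads the coordinate stream of a GROMACS TRR file (single or double
#' precision).  Velocity/force/virial/pressure blocks are skipped.
#'
#' @param path path to a TRR file.
#' @return List with \code{coords} (F x N x 3 array, nm) and \code{box}
#'   (list of 3 x 3 matrices, or \code{NULL} entries when absent).
#' @export
read_trr <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  con <- rawConnection(raw)
  on.exit(close(con))
  rint <- function(k = 1L) readBin(con, "integer", n = k, size = 4L, endian = "big")
  frames <- list(); boxes <- list()
  repeat {
    magic <- rint()
    if (length(magic) == 0L) break
    if (magic != TRR_MAGIC) stopf("%s: bad TRR magic %d (corrupt file?)", path, magic)
    slen <- rint()                           # strlen + 1
    xlen <- rint()
    readBin(con, "raw", n = 4L * ceiling(xlen / 4))
    hdr <- rint(11L)                         # ir,e,box,vir,pres,top,sym,x,v,f,natoms
    box_size <- hdr[3L]; vir_size <- hdr[4L]; pres_size <- hdr[5L]
    x_size <- hdr[8L]; v_size <- hdr[9L]; f_size <- hdr[10L]
    natoms <- hdr[11L]
    rint(2L)                                 # step, nre
    prec <- if (x_size > 0L) x_size / (3L * natoms)
            else if (box_size > 0L) box_size / 9L
            else 4L
    if (!prec %in% c(4L, 8L)) stopf("%s: unsupported TRR precision %s", path, prec)
    rreal <- function(k) readBin(con, "double", n = k, size = prec, endian = "big")
    rreal(2L)                                # t, lambda
    boxmat <- NULL
    if (box_size > 0L) boxmat <- matrix(rreal(9L), 3L, 3L, byrow = TRUE)
    if (vir_size > 0L) rreal(9L)
    if (pres_size > 0L) rreal(9L)
    if (x_size == 0L) stopf("%s: TRR frame without coordinates", path)
    x <- matrix(rreal(3L * natoms), ncol = 3L, byrow = TRUE)
    if (v_size > 0L) rreal(3L * natoms)
    if (f_size > 0L) rreal(3L * natoms)
    frames[[length(frames) + 1L]] <- x
    boxes[[length(boxes) + 1L]] <- boxmat
  }
  if (length(frames) == 0L) stopf("%s: empty TRR file", path)
  n <- nrow(frames[[1L]])
  coords <- array(NA_real_, dim = c(length(frames), n, 3L))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  list(coords = coords, box = boxes)
}

#' Write a DCD trajectory
#'
#' Writes a CHARMM-flavoured DCD (little-endian, no unit cell) that
#' \code{bio3d::read.dcd} and standard MD tooling read back.  Coordinates are
#' taken in nm and stored in Angstrom, the container's native unit.
#'
#' @param coords F x N x 3 array (or N x 3 matrix), nm.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_dcd <- function(coords, path) {
  if (length(dim(coords)) == 2L) coords <- array(coords, dim = c(1L, dim(coords)))
  f <- dim(coords)[1L]; n <- dim(coords)[2L]
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  # header block: "CORD" + 20 control ints (delta stored as float bits)
  wint(84L)
  writeBin(charToRaw("CORD"), con)
  icntrl <- integer(20L)
  icntrl[1L] <- f        # frames
  icntrl[2L] <- 1L       # first step
  icntrl[3L] <- 1L       # save interval
  icntrl[4L] <- f        # last step
  icntrl[20L] <- 24L     # CHARMM version tag
  wint(icntrl[1:9])
  wflt(1)                # delta (arbitrary 1 "ps" per frame)
  wint(icntrl[11:20])
  wint(84L)
  title <- sprintf("%-80s", "Created by cvnet write_dcd")
  wint(4L + 80L); wint(1L); writeBin(charToRaw(title), con); wint(4L + 80L)
  wint(4L); wint(n); wint(4L)
  for (fr in seq_len(f)) {
    for (k in 1:3) {
      wint(4L * n)
      wflt(coords[fr, , k] * 10)   # nm -> Angstrom
      wint(4L * n)
    }
  }
  invisible(path)
}
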