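# Preprocessing: rigid-body superposition onto the reference, box scaling of
# coordinates into [0,1], min-max scaling of the target CV, and the
# training/test split.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' \code{mobile} onto \code{target} with equal atom weights, via SVD of the
#' coordinate covariance with a determinant guard so reflections are never
#' returned.  This is the same fit PLUMED performs for
#' \code{FIT_TO_TEMPLATE ... TYPE=OPTIMAL}, which is why it lives in the
#' package rather than behind a generic alignment helper.
#'
#' @param mobile,target N x 3 coordinate matrices (nm), equal N.
#' @return An object of class \code{superposition}: \code{rotation} (3 x 3,
#'   applied on the right of row vectors), \code{translation} (length 3, nm)
#'   and \code{rmsd_after} (nm).  The fitted coordinates are
#'   \code{mobile \%*\% rotation + translation} (row-wise).
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' s <- kabsch_superpose(a, a)
#' s$rmsd_after  # 0
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3L) {
    stopf("superposition needs two N x 3 matrices with equal N (got %d vs %d atoms)",
          nrow(mobile), nrow(target))
  }
  n <- nrow(mobile)
  mu_m <- colMeans(mobile); mu_t <- colMeans(target)
  pc <- sweep(mobile, 2L, mu_m); qc <- sweep(target, 2L, mu_t)
  h <- crossprod(pc, qc)                 # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  # collinear/degenerate clouds leave the rotation about the point axis free
  if (n >= 3L && sv$d[2L] < 1e-12 * max(sv$d[1L], 1e-300)) {
    warning("degenerate (collinear) coordinates: superposition is not unique",
            call. = FALSE)
  }
  r <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- pc %*% r
  rmsd <- sqrt(mean(rowSums((fitted - qc)^2)))
  structure(list(rotation = r,
                 translation = as.numeric(mu_t - mu_m %*% r),
                 rmsd_after = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param sup a \code{\link{kabsch_superpose}} result.
#' @param coords N x 3 matrix (nm).
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% sup$rotation, 2L, sup$translation, "+")
}

rmsd_raw <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Superpose every frame and scale coordinates into the unit box
#'
#' For each frame: superpose onto the reference (unless \code{nofit}), divide
#' x/y/z by the box edges \code{lx/ly/lz}, and flatten atom-major
#' (x1, y1, z1, x2, ...).  Any scaled coordinate outside \[0, 1\] means the
#' box is too small for that conformation and is an error naming the frame,
#' atom and axis.
#'
#' @param trajectory a \code{\link{load_trajectory}} result.
#' @param reference a \code{\link{load_reference}} result (supplies the box).
#' @param nofit skip the superposition (for pre-fitted trajectories).
#' @return F x 3N feature matrix of class \code{feature_matrix}, entries in
#'   \[0, 1\], with attribute \code{layout = "atom-major"}.
#' @export
fit_and_scale <- function(trajectory, reference, nofit = FALSE) {
  f <- trajectory$frame_count
  n <- reference$atom_count
  if (dim(trajectory$coords)[2L] != n) {
    stopf("trajectory has %d atoms but the reference has %d",
          dim(trajectory$coords)[2L], n)
  }
  l <- box_lengths(reference$box)
  x <- matrix(NA_real_, nrow = f, ncol = 3L * n)
  for (fr in seq_len(f)) {
    frame <- trajectory$coords[fr, , , drop = TRUE]
    if (!nofit) {
      sup <- kabsch_superpose(frame, reference$coords)
      frame <- apply_superposition(sup, frame)
    }
    scaled <- sweep(frame, 2L, l, "/")
    bad <- which(scaled < -1e-9 | scaled > 1 + 1e-9, arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      ax <- c("x", "y", "z")[bad[1L, 2L]]
      stopf(paste0("box too small: frame %d, atom %d, axis %s has fitted ",
                   "coordinate %.4f nm outside [0, %.4f] -- enlarge the box"),
            fr, reference$atom_serials[bad[1L, 1L]], ax,
            frame[bad[1L, 1L], bad[1L, 2L]], l[bad[1L, 2L]])
    }
    x[fr, ] <- as.vector(t(scaled))
  }
  structure(x, layout = "atom-major", class = c("feature_matrix", "matrix", "array"))
}

#' Min-max scale the target CV to \[0, 1\]
#'
#' Network inputs live in \[0, 1\]; scaling the target to the same range keeps
#' sigmoid-family hidden layers out of saturation and makes the loss scale
#' comparable across CVs.  The constants are stored so the exported PLUMED
#' file can map the network output back to original CV units.
#'
#' @param values numeric CV values (>= 2 distinct values required).
#' @return List with \code{scaling} (class \code{target_scaling}: fields
#'   \code{cv_min}, \code{cv_max}) and \code{scaled} (values mapped to
#'   \[0, 1\]).
#' @export
scale_targets <- function(values) {
  if (length(values) < 2L || !all(is.finite(values))) {
    stopf("need at least two finite CV values to scale")
  }
  lo <- min(values); hi <- max(values)
  if (hi <= lo) stopf("degenerate CV: all %d values equal %g", length(values), lo)
  scaling <- structure(list(cv_min = lo, cv_max = hi), class = "target_scaling")
  list(scaling = scaling, scaled = (values - lo) / (hi - lo))
}

#' Map scaled network outputs back to CV units
#' @param scaling a \code{target_scaling}.
#' @param scaled values in scaled space.
#' @return values in original CV units.
#' @export
unscale_targets <- function(scaling, scaled) {
  scaling$cv_min + (scaling$cv_max - scaling$cv_min) * scaled
}

#' Split frames into training (TR) and test (TE) sets
#'
#' \code{floor(test_fraction * frame_count)} frames (at least 1) are labelled
#' TE.  With \code{shuffle = TRUE} (default) TE membership is drawn by a
#' seeded permutation; with \code{shuffle = FALSE} the TE set is the trailing
#' contiguous block of frames (a held-out end of trajectory).
#'
#' @param frame_count number of frames.
#' @param test_fraction fraction in (0, 1); default 0.1.
#' @param shuffle randomise TE membership.
#' @param seed RNG seed for the permutation.
#' @return Character vector of length \code{frame_count} over \{"TR", "TE"\}.
#' @export
split_dataset <- function(frame_count, test_fraction = 0.1, shuffle = TRUE,
                          seed = 1L) {
  if (!is_count(frame_count) || frame_count < 2L) {
    stopf("`frame_count` must be an integer >= 2")
  }
  if (!is.numeric(test_fraction) || length(test_fraction) != 1L ||
      test_fraction <= 0 || test_fraction >= 1) {
    stopf("`test_fraction` must lie strictly between 0 and 1 (got %s)",
          format(test_fraction))
  }
  n_te <- max(1L, as.integer(floor(test_fraction * frame_count)))
  labels <- rep("TR", frame_count)
  if (shuffle) {
    te <- with_seed(seed, sample.int(frame_count, n_te))
  } else {
    te <- seq.int(frame_count - n_te + 1L, frame_count)
  }
  labels[te] <- "TE"
  labels
}
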