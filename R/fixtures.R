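# Synthetic conformer ensembles and oracle collective variables.  These stand
# in for real structure sets (systematically generated ring conformers, long
# folding trajectories) so the whole train -> export -> verify loop runs with
# no external data, while exercising the same I/O, fitting and scaling paths.

#' Generate a synthetic conformer ensemble
#'
#' Two generators are available.  \code{"chain-dihedral"} builds an N-bead
#' chain with fixed bond length (0.15 nm) and fixed bond angle, drawing the
#' dihedral angles of every frame uniformly at random -- a cheap source of
#' the kind of conformational variety a ring or short chain explores.
#' \code{"gaussian-cloud"} perturbs the reference with isotropic Gaussian
#' noise.  Every frame is recentred into the box (conformations whose extent
#' exceeds the box are redrawn; if a conformer cannot fit, that is an error)
#' and then given a random rigid rotation + translation so that the fitting
#' step of the pipeline is genuinely exercised.
#'
#' @param n_atoms number of beads (>= 3).
#' @param n_frames number of frames (>= 10).
#' @param box a \code{\link{box_spec}} all conformers must fit.
#' @param seed RNG seed; the ensemble is reproducible from it.
#' @param mode \code{"chain-dihedral"} or \code{"gaussian-cloud"}.
#' @param cv which oracle CV to tabulate: \code{"rgyr"} (radius of gyration,
#'   nm), \code{"sasa"} (Shrake-Rupley area, nm^2) or \code{"none"}.
#' @param bond_length,bond_angle chain geometry (nm, degrees).
#' @param noise_sd Gaussian-cloud displacement sd (nm).
#' @param sasa_points sphere points per atom for the SASA oracle.
#' @return List of class \code{synthetic_ensemble}: \code{reference}
#'   (a \code{reference_structure}), \code{trajectory} (a \code{trajectory}),
#'   \code{cv_values} (a \code{cv_series} or \code{NULL}), \code{cv_name},
#'   \code{seed}.
#' @export
generate_conformers <- function(n_atoms, n_frames, box, seed = 1L,
                                mode = c("chain-dihedral", "gaussian-cloud"),
                                cv = c("rgyr", "sasa", "none"),
                                bond_length = 0.15, bond_angle = 109.47,
                                noise_sd = 0.05, sasa_points = 500L) {
  mode <- match.arg(mode)
  cv <- match.arg(cv)
  if (!is_count(n_atoms) || n_atoms < 3L) stopf("`n_atoms` must be an integer >= 3")
  if (!is_count(n_frames) || n_frames < 10L) stopf("`n_frames` must be an integer >= 10")
  if (!inherits(box, "box_spec")) stopf("`box` must be a box_spec")
  l <- box_lengths(box)
  coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3L))
  ref_coords <- NULL
  with_seed(seed, {
    # A frame is admissible when, once superposed onto the reference (the
    # orientation the pipeline and PLUMED actually use), it still lies inside
    # the box -- the documented requirement on the box size.
    draw_conformer <- function(check_fit = TRUE) {
      for (try in seq_len(500L)) {
        c0 <- if (mode == "chain-dihedral") {
          build_chain(n_atoms, bond_length, bond_angle,
                      dihedrals = stats::runif(max(0L, n_atoms - 3L), -pi, pi))
        } else {
          ref_coords + matrix(stats::rnorm(3L * n_atoms, sd = noise_sd),
                              n_atoms, 3L)
        }
        centred <- recentre_in_box(c0, l)
        if (is.null(centred)) next
        if (!check_fit) return(centred)
        fitted <- apply_superposition(kabsch_superpose(centred, ref_coords),
                                      centred)
        if (all(fitted >= 0) && all(sweep(fitted, 2L, l, "/") <= 1)) {
          return(centred)
        }
      }
      stopf(paste0("box too small: no %d-atom %s conformer fits a ",
                   "%g x %g x %g nm box after 500 attempts"),
            n_atoms, mode, l[1], l[2], l[3])
    }
    if (mode == "gaussian-cloud") {
      # base structure for the cloud: one compact chain conformer
      ref_coords <- recentre_in_box(
        build_chain(n_atoms, bond_length, bond_angle,
                    dihedrals = rep(pi / 3, max(0L, n_atoms - 3L))), l)
      if (is.null(ref_coords)) {
        stopf("box too small for the %d-atom base chain", n_atoms)
      }
    } else {
      ref_coords <- draw_conformer(check_fit = FALSE)
    }
    for (fr in seq_len(n_frames)) {
      conf <- draw_conformer()
      # random proper rotation (QR of a Gaussian matrix) + translation
      qr_ <- qr(matrix(stats::rnorm(9L), 3L))
      r <- qr.Q(qr_)
      if (det(r) < 0) r[, 1L] <- -r[, 1L]
      shift <- stats::runif(3L, -0.2, 0.2) * l
      coords[fr, , ] <- sweep(conf %*% r, 2L, shift, "+")
    }
  })
  ref <- structure(
    list(atom_count = n_atoms,
         atom_serials = seq_len(n_atoms),
         coords = ref_coords,
         box = box,
         atom = NULL),
    class = "reference_structure")
  traj <- structure(
    list(frame_count = n_frames, coords = coords, source_format = "synthetic"),
    class = "trajectory")
  cv_values <- NULL
  if (cv != "none") {
    vals <- vapply(seq_len(n_frames), function(fr) {
      xyz <- coords[fr, , , drop = TRUE]
      if (cv == "rgyr") radius_of_gyration(xyz)
      else shrake_rupley_sasa(xyz, n_points = sasa_points)
    }, numeric(1))
    cv_values <- structure(list(values = vals, column_index = 2L, labels = NULL),
                           class = "cv_series")
  }
  structure(list(reference = ref, trajectory = traj, cv_values = cv_values,
                 cv_name = cv, seed = as.integer(seed)),
            class = "synthetic_ensemble")
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat(sprintf("<synthetic_ensemble> %d frames x %d atoms, cv = %s, seed = %d\n",
              x$trajectory$frame_count, x$reference$atom_count,
              x$cv_name, x$seed))
  invisible(x)
}

# Bead chain by successive internal-coordinate placement (fixed bond length
# and bond angle, supplied dihedrals).  Returns an n x 3 matrix.
build_chain <- function(n, bond_length, bond_angle_deg, dihedrals) {
  theta <- bond_angle_deg * pi / 180
  xyz <- matrix(0, n, 3L)
  xyz[2L, ] <- c(bond_length, 0, 0)
  if (n >= 3L) {
    xyz[3L, ] <- xyz[2L, ] + bond_length * c(-cos(theta), sin(theta), 0)
  }
  for (i in seq_len(n)[-(1:3)]) {
    phi <- dihedrals[i - 3L]
    # NeRF-style placement relative to atoms i-1, i-2, i-3
    bc <- xyz[i - 1L, ] - xyz[i - 2L, ]; bc <- bc / sqrt(sum(bc^2))
    ab <- xyz[i - 2L, ] - xyz[i - 3L, ]
    nrm <- c(ab[2] * bc[3] - ab[3] * bc[2],
             ab[3] * bc[1] - ab[1] * bc[3],
             ab[1] * bc[2] - ab[2] * bc[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    m <- c(nrm[2] * bc[3] - nrm[3] * bc[2],
           nrm[3] * bc[1] - nrm[1] * bc[3],
           nrm[1] * bc[2] - nrm[2] * bc[1])
    d <- bond_length * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
    xyz[i, ] <- xyz[i - 1L, ] + bc * d[1] + m * d[2] + nrm * d[3]
  }
  xyz
}

# Centre a conformer in the box; NULL if its extent exceeds any edge.
recentre_in_box <- function(xyz, l) {
  span <- apply(xyz, 2L, function(v) max(v) - min(v))
  if (any(span > l)) return(NULL)
  lo <- apply(xyz, 2L, min)
  sweep(xyz, 2L, lo - (l - span) / 2, "-")
}

#' Radius of gyration
#'
#' Mass-less Rg: root-mean-square distance of the atoms from their centroid.
#'
#' @param coords N x 3 matrix, nm.
#' @return Rg in nm.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0)))  # 0.5
#' @export
radius_of_gyration <- function(coords) {
  coords <- as.matrix(coords)
  sqrt(mean(rowSums(sweep(coords, 2L, colMeans(coords))^2)))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic point-counting SASA: each atom is covered with \code{n_points}
#' quasi-uniform points on a sphere of radius \eqn{r_i + probe}; points
#' falling inside any other atom's extended sphere are occluded, and the
#' accessible fraction times \eqn{4\pi(r_i+probe)^2} is summed over atoms.
#' The sphere points come from a deterministic golden-section spiral, so the
#' result is seed-free and exactly reproducible.
#'
#' @param coords N x 3 matrix, nm.
#' @param radii per-atom radii in nm (recycled; default 0.15, carbon-like).
#' @param probe probe radius in nm (default 0.14, water-like).
#' @param n_points sphere points per atom (>= 100).
#' @return Total SASA in nm^2.
#' @examples
#' shrake_rupley_sasa(matrix(0, 1, 3))  # 4*pi*0.29^2
#' @export
shrake_rupley_sasa <- function(coords, radii = 0.15, probe = 0.14,
                               n_points = 1000L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (!is_count(n_points) || n_points < 100L) stopf("`n_points` must be >= 100")
  radii <- rep_len(radii, n)
  if (any(radii <= 0) || probe < 0) stopf("radii must be positive and probe >= 0")
  pts <- golden_spiral_points(n_points)
  ext <- radii + probe
  total <- 0
  for (i in seq_len(n)) {
    sphere <- sweep(pts * ext[i], 2L, coords[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)[-i]) {
      if (!any(free)) break
      d2 <- (sphere[, 1L] - coords[j, 1L])^2 +
            (sphere[, 2L] - coords[j, 2L])^2 +
            (sphere[, 3L] - coords[j, 3L])^2
      free <- free & (d2 >= ext[j]^2)
    }
    total <- total + sum(free) / n_points * 4 * pi * ext[i]^2
  }
  total
}

# n quasi-uniform unit-sphere points on a golden-section spiral.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Linear probe collective variable
#'
#' \eqn{w \cdot x + c} on the flattened feature vector: an exactly
#' representable target for network recovery tests.
#'
#' @param x feature vector (or matrix, samples in rows).
#' @param w weight vector of matching length.
#' @param c intercept.
#' @return Scalar (or vector for matrix input).
#' @export
linear_cv <- function(x, w, c = 0) {
  if (is.matrix(x)) {
    if (ncol(x) != length(w)) stopf("w has length %d but x has %d columns",
                                    length(w), ncol(x))
    drop(x %*% w) + c
  } else {
    if (length(x) != length(w)) stopf("w and x lengths differ")
    sum(x * w) + c
  }
}

#' Write a synthetic ensemble through the on-disk formats
#'
#' Materialises the ensemble as the three input files the pipeline reads --
#' reference PDB, trajectory (multi-model PDB, DCD or TRR) and a
#' whitespace-separated CV table (frame id in column 1, CV in column 2) --
#' so tests exercise the real I/O path.
#'
#' @param ensemble a \code{\link{generate_conformers}} result.
#' @param dir output directory (created if needed).
#' @param traj_format "pdb", "dcd" or "trr".
#' @return Named list of the three file paths.
#' @export
write_ensemble <- function(ensemble, dir, traj_format = c("pdb", "dcd", "trr")) {
  traj_format <- match.arg(traj_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref_path <- file.path(dir, "reference.pdb")
  write_pdb_nm(ensemble$reference$coords, ref_path,
               serials = ensemble$reference$atom_serials)
  traj_path <- file.path(dir, paste0("traj.", traj_format))
  switch(traj_format,
         pdb = write_pdb_nm(ensemble$trajectory$coords, traj_path,
                            serials = ensemble$reference$atom_serials),
         dcd = write_dcd(ensemble$trajectory$coords, traj_path),
         trr = write_trr(ensemble$trajectory$coords, traj_path,
                         box = ensemble$reference$box))
  cv_path <- file.path(dir, "cv_table.txt")
  if (is.null(ensemble$cv_values)) stopf("ensemble carries no CV values")
  writeLines(sprintf("%d %.10g", seq_along(ensemble$cv_values$values),
                     ensemble$cv_values$values), cv_path)
  list(reference = ref_path, trajectory = traj_path, cv_table = cv_path)
}
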