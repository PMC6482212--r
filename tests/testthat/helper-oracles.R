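# Shared fixtures and independent oracles used across test files.

# Small ensemble cached per session so several files can reuse it cheaply.
tiny_cloud <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_conformers(6, 100, box_spec(1, 1, 1), seed = 42,
                                    mode = "gaussian-cloud", cv = "rgyr")
    }
    cache
  }
})

# Independent RMSD minimisation: coarse Euler-angle grid followed by
# Nelder-Mead refinement.  Shares no code with the SVD route.
grid_rmsd <- function(mobile, target, n_grid = 14L) {
  pc <- sweep(mobile, 2L, colMeans(mobile))
  qc <- sweep(target, 2L, colMeans(target))
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    rz1 <- matrix(c(ca[1], sa[1], 0, -sa[1], ca[1], 0, 0, 0, 1), 3)
    ry  <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3)
    rz2 <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3)
    rz1 %*% ry %*% rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((pc %*% rot(ang) - qc)^2)))
  best <- c(0, 0, 0); best_v <- obj(best)
  as_ <- seq(0, 2 * pi, length.out = n_grid + 1L)[-1L]
  bs <- seq(0, pi, length.out = n_grid)
  for (a in as_) for (b in bs) for (g in as_) {
    v <- obj(c(a, b, g))
    if (v < best_v) { best_v <- v; best <- c(a, b, g) }
  }
  stats::optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))$value
}

rmsd_of <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Central finite differences of the network output w.r.t. the inputs.
fd_gradient <- function(net, x, h = 1e-5) {
  vapply(seq_along(x), function(k) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
    (forward(net, xp) - forward(net, xm)) / (2 * h)
  }, numeric(1))
}

# Exact SASA of two equal spheres of extended radius R at centre distance d:
# each sphere loses a cap of height h = R - d/2.
two_sphere_sasa <- function(d, R) {
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# Random rigid motion of a frame (proper rotation + translation).
random_rigid <- function(frame, shift_scale = 1) {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(frame %*% q, 2, stats::runif(3, -shift_scale, shift_scale), "+")
}

# A seeded random architecture for property sweeps.
random_net <- function(n_inputs, seed) {
  with_seed_t(seed, {
    nl <- sample(1:3, 1)
    hidden <- sample(2:6, nl, replace = TRUE)
    acts <- sample(c("sigmoid", "tanh", "linear", "relu", "softsign", "elu"),
                   nl, replace = TRUE)
    init_network(n_inputs, hidden, acts, seed = seed)
  })
}

# testthat-side analogue of the package's seed guard.
with_seed_t <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}
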