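# Independent oracles used across the suite. These deliberately avoid the
# package's own linear-algebra paths: rotations are rebuilt from scratch and
# the rigid fit is re-derived by generic numeric minimization.

# rotation matrices built independently of the package
o_rx <- function(deg) {
  a <- deg * pi / 180
  rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
}
o_ry <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
}
o_rz <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}
o_rot_zyx <- function(rz, ry, rx) o_rz(rz) %*% o_ry(ry) %*% o_rx(rx)

o_random_rigid <- function() {
  rigid_transform(o_rot_zyx(runif(1, -180, 180), runif(1, -89, 89),
                            runif(1, -180, 180)),
                  runif(3, -100, 100))
}

# mean squared residual of a 6-parameter rigid map on paired points
o_cost <- function(par, moving, fixed) {
  R <- o_rot_zyx(par[1], par[2], par[3])
  res <- moving %*% t(R) + matrix(par[4:6], nrow(moving), 3, byrow = TRUE) - fixed
  mean(rowSums(res^2))
}

# brute-force rigid fit: generic numeric minimization over the 6 parameters,
# multi-started to escape local minima of the angle parameterization
o_bruteforce_fre <- function(moving, fixed, n_starts = 6) {
  starts <- rbind(rep(0, 6),
                  matrix(c(runif(5 * 3, -180, 180), runif(5 * 3, -50, 50)),
                         5, 6)[, c(1, 2, 3, 4, 5, 6)])
  best <- Inf
  for (i in seq_len(min(n_starts, nrow(starts)))) {
    fit <- optim(starts[i, ], o_cost, moving = moving, fixed = fixed,
                 method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    fit <- optim(fit$par, o_cost, moving = moving, fixed = fixed,
                 method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
    if (fit$value < best) best <- fit$value
  }
  sqrt(best)
}

# tiny test volume with a linear intensity ramp in physical coordinates
o_ramp_volume <- function(shape = c(12, 11, 10), spacing = c(0.8, 1.1, 1.4),
                          origin = c(-3, 2, 5), coef = c(2, -1, 0.5), const = 7) {
  idx <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                               k = 0:(shape[3] - 1)))
  p <- sweep(idx, 2, spacing, "*")
  p <- sweep(p, 2, origin, "+")
  volume3d(array(p %*% coef + const, shape), spacing, origin)
}

# all 0-based voxel indices of a grid, fastest axis first (column-major)
o_grid_idx <- function(shape) {
  as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                        k = 0:(shape[3] - 1)))
}
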