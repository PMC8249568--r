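# Shared fixtures: small geometries built in code.

straight_frame <- function(n = 11L, length = 10, radius = 1.5,
                           phase = "diastasis", time_index = 0L) {
  s <- seq(0, length, length.out = n)
  vessel_frame(cbind(0, 0, s), rep(radius, n), phase = phase,
               time_index = time_index)
}

# gently bent tube frame (breaks axial/rotational symmetry so that matching
# optima are unique)
bent_frame <- function(n = 41L, length = 20, radius = 1, amp = 1.5,
                       phase = "diastasis", time_index = 0L) {
  s <- seq(0, length, length.out = n)
  x <- amp * sin(pi * s / length)
  vessel_frame(cbind(x, 0, s), rep(radius, n), phase = phase,
               time_index = time_index)
}

# quarter-circle arc of radius R in the xy-plane, densely sampled
arc_points <- function(R = 10, n = 100L) {
  th <- seq(0, pi / 2, length.out = n)
  cbind(R * cos(th), R * sin(th), 0)
}

rigid_transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  flat <- matrix(mesh$nodes, ncol = 3L) %*% t(R)
  flat <- sweep(flat, 2L, t, `+`)
  mesh$nodes <- array(flat, dim = dim(mesh$nodes))
  mesh
}

rot3 <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# minimal propagation object for strain-series tests
fake_propagation <- function(grids, arclength,
                             phases = NULL, time_index = NULL) {
  K <- length(grids)
  structure(list(grids = grids, fields = NULL, closure_field = NULL,
                 closure_residual = 0, diastasis_mesh = NULL,
                 arclength = arclength,
                 phases = phases %||% c("diastasis", rep("other", K - 1L)),
                 time_index = time_index %||% (seq_len(K) - 1L)),
            class = "sws_propagation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

inflate_grid <- function(grid, factor) {
  ctr <- apply(grid, c(1L, 3L), mean)
  out <- grid
  for (d in 1:3) out[, , d] <- ctr[, d] + factor * (grid[, , d] - ctr[, d])
  out
}
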