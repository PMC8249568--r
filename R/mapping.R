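# Energy-minimizing node correspondence between consecutive configurations.
# Because all meshes of a sequence share identical node dimensions, the
# matching search space reduces to a continuous axial re-parameterization
# shift plus a circumferential twist offset; the correspondence minimizing a
# potential-energy functional (membrane deformation energy plus a normalized
# squared-displacement kinetic proxy) defines the one-to-one node mapping and
# hence the displacement field.

# circumferential shift (delta in node spacings, continuous, periodic) and
# axial shift (a_off in mm, linear, extrapolating at the ends) of a grid
resample_grid <- function(nodes, arclength, a_off, delta) {
  dims <- dim(nodes)
  L <- dims[1L]; C <- dims[2L]
  j0 <- floor(delta)
  f <- delta - j0
  idx1 <- ((seq_len(C) - 1L + j0) %% C) + 1L
  idx2 <- (idx1 %% C) + 1L
  shifted <- (1 - f) * nodes[, idx1, , drop = FALSE] +
    f * nodes[, idx2, , drop = FALSE]
  if (f > 0) {
    # chord interpolation between neighbouring nodes pulls points inside the
    # ring; restore the linearly interpolated node-to-centroid distance so a
    # fractional twist cannot masquerade as circumferential compression
    ctr <- apply(nodes, c(1L, 3L), mean)
    rad <- function(g) sqrt((g[, , 1L] - ctr[, 1L])^2 +
                              (g[, , 2L] - ctr[, 2L])^2 +
                              (g[, , 3L] - ctr[, 3L])^2)
    target <- (1 - f) * rad(nodes[, idx1, , drop = FALSE]) +
      f * rad(nodes[, idx2, , drop = FALSE])
    scale <- target / rad(shifted)
    for (d in 1:3)
      shifted[, , d] <- ctr[, d] + scale * (shifted[, , d] - ctr[, d])
  }
  p <- arclength + a_off
  i0 <- pmin(pmax(findInterval(p, arclength, all.inside = TRUE), 1L), L - 1L)
  g <- (p - arclength[i0]) / (arclength[i0 + 1L] - arclength[i0])
  out <- array(0, dims)
  for (d in 1:3)
    out[, , d] <- (1 - g) * shifted[i0, , d] + g * shifted[i0 + 1L, , d]
  out
}

as_node_grid <- function(mesh) {
  if (inherits(mesh, "sws_mesh")) mesh$nodes else {
    stopifnot(is.array(mesh), length(dim(mesh)) == 3L, dim(mesh)[3L] == 3L)
    mesh
  }
}

#' Potential energy of a candidate node matching
#'
#' `alpha_deform` weighs the Mooney-Rivlin membrane deformation energy of the
#' elements under the matched correspondence,
#' `sum(W(element stretch) * A_ref)` with nominal normal-tissue constants,
#' and `alpha_kinetic` weighs the mean squared node displacement normalized
#' by the nominal diameter squared. At the default weights the deformation
#' term dominates by construction; the kinetic proxy acts as a tie-breaker
#' that selects the physically smallest motion among deformation-equivalent
#' (isometric) matches.
#'
#' @param mesh_a reference configuration: an `sws_mesh` or an L x C x 3 node
#'   grid.
#' @param mesh_b deformed configuration: an `sws_mesh` with the same `(L, C)`.
#' @param matching list with `axial_offset` (mm) and `circumferential_offset`
#'   (rad).
#' @param weights numeric pair `(alpha_deform, alpha_kinetic)`.
#' @param material `sws_material` used for the deformation term (nominal
#'   normal tissue by default).
#' @param d_nom nominal diameter, mm; defaults to the mean diameter of
#'   `mesh_b`.
#' @return scalar energy (dimensionless, >= 0); `Inf` for a degenerate
#'   matching.
#' @export
matching_energy <- function(mesh_a, mesh_b,
                            matching = list(axial_offset = 0,
                                            circumferential_offset = 0),
                            weights = c(1, 1e-3),
                            material = default_materials()$normal,
                            d_nom = NULL) {
  nodes_a <- as_node_grid(mesh_a)
  stopifnot(inherits(mesh_b, "sws_mesh"))
  if (!all(dim(nodes_a)[1:2] == c(mesh_b$L, mesh_b$C)))
    stop("meshes must share identical node dimensions (L, C)", call. = FALSE)
  if (is.null(d_nom)) d_nom <- 2 * mean(mesh_b$radius)
  delta <- (matching$circumferential_offset %% (2 * pi)) / (2 * pi / mesh_b$C)
  matched <- resample_grid(mesh_b$nodes, mesh_b$arclength,
                           matching$axial_offset, delta)
  energy_of_match(nodes_a, matched, weights, material, d_nom)
}

energy_of_match <- function(nodes_a, matched, weights, material, d_nom,
                            A = NULL) {
  disp2 <- sum((matched - nodes_a)^2)
  kinetic <- disp2 / prod(dim(nodes_a)[1:2]) / d_nom^2
  deform <- tryCatch({
    Fg <- grid_deformation_gradients(nodes_a, matched, A = A)
    st <- gradient_stretches(Fg)
    W <- mooney_rivlin_energy(st$lambda1, st$lambda2, material)
    sum(W * Fg$area)
  }, error = function(e) Inf)
  e <- weights[[1L]] * deform + weights[[2L]] * kinetic
  if (!is.finite(e)) Inf else e
}

default_search <- function() {
  list(weights = c(1, 1e-3), axial_halfwidth = 2, n_axial = 5L,
       refine = TRUE,
       maxit = 200L, reltol = 1e-10, refine_min_improvement = 0.01,
       material = default_materials()$normal)
}

#' Energy-minimizing displacement field between two configurations
#'
#' Two-stage minimization over the matching: an exhaustive coarse grid over
#' all `C` circumferential node offsets crossed with axial offsets spanning
#' +/- `axial_halfwidth` ring spacings, followed by continuous Nelder-Mead
#' refinement of both offsets. Ties in the discrete stage are broken toward
#' the smaller-magnitude offset, then the smaller circumferential index.
#'
#' @param mesh_a reference configuration (`sws_mesh` or L x C x 3 grid).
#' @param mesh_b deformed configuration (`sws_mesh`, same `(L, C)`).
#' @param search list overriding [default_search()] entries: `weights`,
#'   `axial_halfwidth` (ring spacings), `n_axial`, `maxit`, `reltol`,
#'   `material`.
#' @return object of class `sws_displacement_field`: list with `vectors`
#'   (L x C x 3 displacement array, mm), `matched_grid` (the matched deformed
#'   node positions), `energy`, `matching` (`axial_offset` mm,
#'   `circumferential_offset` rad in `[0, 2*pi)`), `from_index`, `to_index`.
#' @export
map_displacements <- function(mesh_a, mesh_b, search = list()) {
  cfg <- utils::modifyList(default_search(), search)
  nodes_a <- as_node_grid(mesh_a)
  stopifnot(inherits(mesh_b, "sws_mesh"))
  if (!all(dim(nodes_a)[1:2] == c(mesh_b$L, mesh_b$C)))
    stop("meshes must share identical node dimensions (L, C)", call. = FALSE)
  L <- mesh_b$L; C <- mesh_b$C
  d_nom <- 2 * mean(mesh_b$radius)
  spacing <- mean(diff(mesh_b$arclength))
  A_ref <- grid_edge_coords(nodes_a)
  ener <- function(a_off, delta)
    energy_of_match(nodes_a,
                    resample_grid(mesh_b$nodes, mesh_b$arclength, a_off, delta),
                    cfg$weights, cfg$material, d_nom, A = A_ref)

  # exhaustive discrete stage
  deltas <- 0:(C - 1L)
  a_offs <- seq(-cfg$axial_halfwidth, cfg$axial_halfwidth,
                length.out = cfg$n_axial) * spacing
  grid <- expand.grid(delta = deltas, a = a_offs)
  grid$e <- mapply(function(a, d) ener(a, d), grid$a, grid$delta)
  dsig <- ifelse(grid$delta > C / 2, grid$delta - C, grid$delta)
  emin <- min(grid$e)
  tol <- 1e-12 * (1 + abs(emin))
  cand <- which(grid$e <= emin + tol)
  cand <- cand[order(abs(dsig[cand]) + abs(grid$a[cand]) / spacing,
                     abs(dsig[cand]), grid$delta[cand])]
  best <- cand[1L]
  a0 <- grid$a[best]; d0 <- dsig[best]

  # continuous refinement (offsets in units of spacing / nodes); the refined
  # matching is adopted only when it lowers the energy by a meaningful
  # relative margin -- near-ties keep the smaller discrete offset, extending
  # the tie-break rule to the shallow continuous landscape
  if (cfg$refine) {
    obj <- function(x) ener(x[1L] * spacing, x[2L] %% C)
    opt <- stats::optim(c(a0 / spacing, d0), obj, method = "Nelder-Mead",
                        control = list(maxit = cfg$maxit, reltol = cfg$reltol,
                                       warn.1d.NelderMead = FALSE))
    accept <- (grid$e[best] - opt$value) >
      cfg$refine_min_improvement * abs(grid$e[best])
  } else accept <- FALSE
  x <- if (accept) opt$par else c(a0 / spacing, d0)
  e_final <- if (accept) opt$value else grid$e[best]
  a_fin <- x[1L] * spacing
  d_fin <- x[2L] %% C
  matched <- resample_grid(mesh_b$nodes, mesh_b$arclength, a_fin, d_fin)
  structure(list(vectors = matched - nodes_a,
                 matched_grid = matched,
                 energy = e_final,
                 matching = list(axial_offset = a_fin,
                                 circumferential_offset = d_fin * 2 * pi / C),
                 from_index = if (inherits(mesh_a, "sws_mesh")) mesh_a$time_index else NA_integer_,
                 to_index = mesh_b$time_index),
            class = "sws_displacement_field")
}

#' Propagate displacement mapping around the cardiac cycle
#'
#' Starting from the diastasis configuration, each consecutive frame is
#' matched against the previously matched configuration, making the node
#' correspondence transitive through the cycle; finally the last frame is
#' matched back onto diastasis and the cycle-closure residual (RMS distance
#' of the composed configuration from the diastasis nodes) is reported, not
#' corrected.
#'
#' @param sequence an `sws_cardiac_sequence`, or a plain list of
#'   `sws_vessel_frame`s starting at diastasis.
#' @param search see [map_displacements()].
#' @param L,C mesh dimensions; default to the sequence's own.
#' @return object of class `sws_propagation`: list with `grids` (per-frame
#'   matched L x C x 3 node grids, diastasis first), `fields` (per-pair
#'   `sws_displacement_field`s), `closure_field`, `closure_residual` (mm),
#'   `diastasis_mesh`, `arclength`, `phases`, `time_index`.
#' @export
propagate_cycle <- function(sequence, search = list(), L = NULL, C = NULL) {
  frames <- if (inherits(sequence, "sws_cardiac_sequence")) sequence$frames
  else sequence
  if (length(frames) < 2L)
    stop("a cardiac sequence needs at least 2 frames", call. = FALSE)
  if (frames[[1L]]$phase != "diastasis")
    stop("the first frame must be diastasis", call. = FALSE)
  if (is.null(L)) L <- if (inherits(sequence, "sws_cardiac_sequence")) sequence$L else 101L
  if (is.null(C)) C <- if (inherits(sequence, "sws_cardiac_sequence")) sequence$C else 32L
  meshes <- lapply(frames, build_structured_mesh, L = L, C = C)
  K <- length(frames)
  grids <- vector("list", K)
  fields <- vector("list", K - 1L)
  grids[[1L]] <- meshes[[1L]]$nodes
  for (k in 2:K) {
    fld <- tryCatch(map_displacements(grids[[k - 1L]], meshes[[k]], search),
                    error = function(e)
                      stop(sprintf("mapping failed for frame pair (%d, %d): %s",
                                   k - 1L, k, conditionMessage(e)), call. = FALSE))
    fields[[k - 1L]] <- fld
    grids[[k]] <- fld$matched_grid
  }
  closure <- map_displacements(grids[[K]], meshes[[1L]], search)
  residual <- sqrt(mean(rowSums(
    matrix(closure$matched_grid - grids[[1L]], ncol = 3L)^2)))
  structure(list(grids = grids, fields = fields, closure_field = closure,
                 closure_residual = residual,
                 diastasis_mesh = meshes[[1L]],
                 arclength = meshes[[1L]]$arclength,
                 phases = vapply(frames, `[[`, "", "phase"),
                 time_index = vapply(frames, function(f) as.integer(f$time_index), 1L)),
            class = "sws_propagation")
}

#' Predict a held-out frame's centerline from the rest of the cycle
#'
#' The sequence without frame `k` is propagated around the cycle; the node
#' grid at frame `k`'s cycle fraction is interpolated piecewise-linearly in
#' time between the matched grids of its neighbors (using the cycle-closure
#' configuration when `k` is the last frame), and the predicted centerline is
#' the ring-centroid curve of the interpolated grid.
#'
#' @param sequence an `sws_cardiac_sequence` with at least 4 frames.
#' @param k index of the held-out frame (not 1: diastasis is the reference
#'   and cannot be held out).
#' @param search see [map_displacements()].
#' @return object of class `sws_prediction`: list with `centerline` (an
#'   `sws_centerline`), `grid` (predicted L x C x 3 nodes), `k`, `tau`
#'   (cycle fraction).
#' @export
predict_frame <- function(sequence, k, search = list()) {
  stopifnot(inherits(sequence, "sws_cardiac_sequence"))
  K <- length(sequence$frames)
  if (k == 1L)
    stop("the diastasis reference frame cannot be held out", call. = FALSE)
  if (K - 1L < 3L)
    stop("need at least 3 frames besides the held-out one", call. = FALSE)
  if (k < 1L || k > K) stop("frame index out of range", call. = FALSE)
  keep <- setdiff(seq_len(K), k)
  sub <- sequence
  sub$frames <- sequence$frames[keep]
  prop <- propagate_cycle(sub, search)
  tau <- (seq_len(K) - 1L) / K          # cycle fraction per original frame
  tau_keep <- tau[keep]
  prev_pos <- max(which(tau_keep < tau[k]))
  g_prev <- prop$grids[[prev_pos]]
  if (k == K) {
    g_next <- prop$closure_field$matched_grid
    tau_next <- 1
  } else {
    g_next <- prop$grids[[prev_pos + 1L]]
    tau_next <- tau_keep[prev_pos + 1L]
  }
  f <- (tau[k] - tau_keep[prev_pos]) / (tau_next - tau_keep[prev_pos])
  grid <- (1 - f) * g_prev + f * g_next
  ctr <- apply(grid, c(1L, 3L), mean)
  structure(list(centerline = centerline(ctr), grid = grid, k = k,
                 tau = tau[k]),
            class = "sws_prediction")
}
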