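# Vessel geometry: centerlines, structured tubular surface meshes,
# diameter-stenosis profiling. Units are millimetres throughout; the ring
# index runs from the proximal (ostial) end to the distal end.

#' Construct a vessel centerline
#'
#' A centerline is an ordered polyline in 3D with a cumulative arclength
#' coordinate. Arclength starts at 0 at the proximal (ostial) end.
#'
#' @param points numeric matrix, n x 3, ordered 3D coordinates in mm.
#' @return An object of class `sws_centerline` with elements `points`
#'   (n x 3 matrix) and `arclength` (length-n numeric, strictly increasing,
#'   first element 0).
#' @export
centerline <- function(points) {
  points <- as_point_matrix(points)
  if (nrow(points) < 4L)
    stop("invalid geometry: a centerline needs at least 4 points", call. = FALSE)
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0))
    stop("invalid geometry: consecutive centerline points must be distinct",
         call. = FALSE)
  structure(list(points = points, arclength = c(0, cumsum(seg))),
            class = "sws_centerline")
}

as_point_matrix <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L || anyNA(points) || any(!is.finite(points)))
    stop("invalid geometry: points must be a finite n x 3 matrix", call. = FALSE)
  dimnames(points) <- NULL
  points
}

#' Resample a polyline to equal arclength spacing
#'
#' The input polyline is treated as piecewise linear; `n` points are placed at
#' equal arclength intervals along it, preserving both endpoints.
#'
#' @param points numeric matrix, m x 3 (m >= 2, not all coincident).
#' @param n number of output points (>= 4).
#' @return An `sws_centerline` with `n` points.
#' @export
resample_centerline <- function(points, n) {
  points <- as_point_matrix(points)
  # drop exactly repeated consecutive points (common in digitized curves)
  if (nrow(points) >= 2L) {
    keep <- c(TRUE, rowSums((points[-1L, , drop = FALSE] -
                               points[-nrow(points), , drop = FALSE])^2) > 0)
    points <- points[keep, , drop = FALSE]
  }
  if (nrow(points) < 2L)
    stop("invalid geometry: need at least 2 distinct points to resample",
         call. = FALSE)
  if (n < 4L) stop("n must be at least 4", call. = FALSE)
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  target <- seq(0, s[length(s)], length.out = n)
  out <- cbind(stats::approx(s, points[, 1L], xout = target)$y,
               stats::approx(s, points[, 2L], xout = target)$y,
               stats::approx(s, points[, 3L], xout = target)$y)
  centerline(out)
}

#' Rotation-minimizing orthonormal frames along a centerline
#'
#' Tangents are normalized arclength derivatives (central differences in the
#' interior, one-sided at the ends). The pair of normals is propagated by the
#' double-reflection rotation-minimizing-frame update, which transports the
#' first normal along the curve without torsion-induced spin, so that
#' circumferential mesh nodes carry no spurious twist.
#'
#' @param cl an `sws_centerline`.
#' @return list with n x 3 matrices `tangent`, `normal1`, `normal2`;
#'   each row triple is orthonormal.
#' @export
local_frames <- function(cl) {
  stopifnot(inherits(cl, "sws_centerline"))
  p <- cl$points
  n <- nrow(p)
  tg <- matrix(0, n, 3L)
  tg[1L, ] <- p[2L, ] - p[1L, ]
  tg[n, ] <- p[n, ] - p[n - 1L, ]
  if (n > 2L) tg[2:(n - 1L), ] <- p[3:n, , drop = FALSE] - p[1:(n - 2L), , drop = FALSE]
  tg <- tg / sqrt(rowSums(tg^2))

  nm1 <- matrix(0, n, 3L)
  nm2 <- matrix(0, n, 3L)
  # seed normal: fixed world axis projected off the first tangent, so that
  # meshes of slightly rotated frames keep nearly aligned node labelling
  seed <- if (abs(tg[1L, 1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- seed - sum(seed * tg[1L, ]) * tg[1L, ]
  nm1[1L, ] <- v / sqrt(sum(v^2))
  nm2[1L, ] <- cross3(tg[1L, ], nm1[1L, ])
  for (i in seq_len(n - 1L)) {
    # double-reflection update (reflection in the chord bisector plane,
    # then in the bisector of the reflected and next tangent)
    v1 <- p[i + 1L, ] - p[i, ]
    c1 <- sum(v1 * v1)
    rL <- nm1[i, ] - (2 / c1) * sum(v1 * nm1[i, ]) * v1
    tL <- tg[i, ] - (2 / c1) * sum(v1 * tg[i, ]) * v1
    v2 <- tg[i + 1L, ] - tL
    c2 <- sum(v2 * v2)
    r2 <- if (c2 < 1e-300) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # re-orthonormalize against accumulated round-off
    r2 <- r2 - sum(r2 * tg[i + 1L, ]) * tg[i + 1L, ]
    nm1[i + 1L, ] <- r2 / sqrt(sum(r2^2))
    nm2[i + 1L, ] <- cross3(tg[i + 1L, ], nm1[i + 1L, ])
  }
  list(tangent = tg, normal1 = nm1, normal2 = nm2)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Construct a vessel frame (one cardiac time point)
#'
#' A vessel frame couples a centerline with a circular lumen cross-section
#' radius at every centerline point and a cardiac-phase label.
#'
#' @param cl an `sws_centerline`, or an n x 3 matrix of points.
#' @param radius per-point lumen radius in mm (all > 0), length n.
#' @param phase one of `"diastasis"`, `"end_diastole"`, `"early_systole"`,
#'   `"end_systole"`, `"early_diastole"`, `"other"`.
#' @param time_index integer frame order within the cardiac cycle.
#' @return An object of class `sws_vessel_frame`.
#' @export
vessel_frame <- function(cl, radius, phase = "other", time_index = 0L) {
  if (!inherits(cl, "sws_centerline")) cl <- centerline(cl)
  radius <- as.numeric(radius)
  if (length(radius) != nrow(cl$points))
    stop("radius must have one value per centerline point", call. = FALSE)
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("invalid geometry: all lumen radii must be finite and > 0", call. = FALSE)
  phase <- match.arg(phase, cardiac_phases())
  structure(list(centerline = cl, radius = radius, phase = phase,
                 time_index = as.integer(time_index)),
            class = "sws_vessel_frame")
}

cardiac_phases <- function() {
  c("diastasis", "end_diastole", "early_systole", "end_systole",
    "early_diastole", "other")
}

#' Build a structured tubular surface mesh for a vessel frame
#'
#' The centerline is resampled to `L` rings at equal arclength; at ring `i`,
#' `C` nodes are placed on the circle of the local lumen radius in the
#' rotation-minimizing normal plane:
#' `node(i,j) = c(s_i) + r_i (cos(theta_j) n1_i + sin(theta_j) n2_i)`,
#' `theta_j = 2*pi*j/C`. Quadrilateral elements are implicit between
#' consecutive rings with circumferential wrap-around, so every mesh of a
#' cardiac sequence built with the same `(L, C)` has identical node
#' dimensions and a trivially consistent element topology.
#'
#' @param frame an `sws_vessel_frame`.
#' @param L number of rings (>= 4). Default 101 gives ~0.5 mm axial spacing on
#'   a 50 mm vessel.
#' @param C nodes per ring (>= 8). Default 32.
#' @return An object of class `sws_mesh`: list with `nodes` (L x C x 3 array),
#'   `L`, `C`, `arclength` (ring arclength coordinates), `radius` (per-ring
#'   lumen radius), `phase`, `time_index`, and `self_intersecting` flag.
#' @export
build_structured_mesh <- function(frame, L = 101L, C = 32L) {
  stopifnot(inherits(frame, "sws_vessel_frame"))
  if (L < 4L) stop("L must be at least 4", call. = FALSE)
  if (C < 8L) stop("C must be at least 8", call. = FALSE)
  cl0 <- frame$centerline
  cl <- resample_centerline(cl0$points, L)
  r <- stats::approx(cl0$arclength, frame$radius, xout = cl$arclength,
                     rule = 2)$y
  fr <- local_frames(cl)
  theta <- 2 * pi * (seq_len(C) - 1L) / C
  ct <- cos(theta); st <- sin(theta)
  nodes <- array(0, dim = c(L, C, 3L))
  for (k in 1:3) {
    nodes[, , k] <- cl$points[, k] +
      r * (outer(fr$normal1[, k], ct) + outer(fr$normal2[, k], st))
  }
  # curvature check: tube self-intersects where radius exceeds the local
  # radius of curvature of the centerline
  kappa <- polyline_curvature(cl$points, cl$arclength)
  selfint <- any(r * kappa > 1)
  if (selfint)
    warning("tube radius exceeds local radius of curvature; mesh may self-intersect",
            call. = FALSE)
  structure(list(nodes = nodes, L = L, C = C,
                 arclength = cl$arclength, radius = r,
                 phase = frame$phase, time_index = frame$time_index,
                 self_intersecting = selfint),
            class = "sws_mesh")
}

polyline_curvature <- function(p, s) {
  n <- nrow(p)
  kap <- numeric(n)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      d2 <- (p[i + 1L, ] - 2 * p[i, ] + p[i - 1L, ]) /
        ((0.5 * (s[i + 1L] - s[i - 1L]))^2)
      kap[i] <- sqrt(sum(d2^2))
    }
    kap[1L] <- kap[2L]; kap[n] <- kap[n - 1L]
  }
  kap
}

#' Ring centroids of a structured mesh
#'
#' @param mesh an `sws_mesh`.
#' @return L x 3 matrix of per-ring node centroids (recovers the generating
#'   centerline for circular cross-sections).
#' @export
mesh_centerline <- function(mesh) {
  stopifnot(inherits(mesh, "sws_mesh"))
  apply(mesh$nodes, c(1L, 3L), mean)
}

#' Per-ring mean node-to-centroid distance of a structured mesh
#'
#' @param mesh an `sws_mesh`.
#' @return numeric vector of length L (recovers the lumen radii for circular
#'   cross-sections).
#' @export
mesh_radii <- function(mesh) {
  ctr <- mesh_centerline(mesh)
  d2 <- (mesh$nodes[, , 1L] - ctr[, 1L])^2 +
    (mesh$nodes[, , 2L] - ctr[, 2L])^2 +
    (mesh$nodes[, , 3L] - ctr[, 3L])^2
  rowMeans(sqrt(d2))
}

#' Percent-diameter-stenosis profile and normal/stenotic segmentation
#'
#' The reference (healthy) diameter is interpolated linearly between the
#' proximal and distal lesion shoulders, detected as the nearest rings on each
#' side of the global minimum-diameter ring where the diameter recovers to at
#' least 90% of that side's segmental median. Rings outside the shoulders use
#' their own diameter as reference. Percent diameter stenosis is
#' `(1 - d/d_ref) * 100`, clipped at 0; rings above `threshold` are labelled
#' stenotic.
#'
#' @param frame an `sws_vessel_frame`, or an `sws_mesh` (profiled at its ring
#'   resolution).
#' @param threshold percent-diameter-stenosis cut-off in (0, 100) separating
#'   normal from stenotic rings. Default 20.
#' @param recovery_frac fraction of the segmental median diameter that counts
#'   as shoulder recovery. Default 0.9.
#' @return An object of class `sws_stenosis_profile`: list with `percent_ds`,
#'   `reference_diameter`, `labels` (`"normal"`/`"stenotic"`), `throat`
#'   (index of the minimum-diameter ring), `shoulders` (proximal/distal ring
#'   indices), `threshold`, `arclength`.
#' @export
compute_stenosis_profile <- function(frame, threshold = 20, recovery_frac = 0.9) {
  if (inherits(frame, "sws_mesh")) {
    radius <- frame$radius
    arclength <- frame$arclength
  } else {
    stopifnot(inherits(frame, "sws_vessel_frame"))
    radius <- frame$radius
    arclength <- frame$centerline$arclength
  }
  if (threshold <= 0 || threshold >= 100)
    stop("threshold must lie in (0, 100)", call. = FALSE)
  d <- 2 * radius
  n <- length(d)
  imin <- which.min(d)

  shoulder <- function(side) {
    idx <- if (side == "prox") rev(seq_len(max(imin - 1L, 0L))) else
      if (imin < n) (imin + 1L):n else integer(0)
    if (!length(idx)) return(if (side == "prox") 1L else n)
    med <- stats::median(d[idx])
    hit <- which(d[idx] >= recovery_frac * med)
    if (!length(hit)) return(if (side == "prox") 1L else n)
    # walk outward past the recovery point up to the local diameter maximum,
    # so the reference line anchors at the healthy rim of the taper
    k <- hit[1L]
    while (k < length(idx) && d[idx[k + 1L]] > d[idx[k]] + 1e-12) k <- k + 1L
    idx[k]
  }
  ip <- shoulder("prox"); id <- shoulder("dist")

  ref <- d
  if (id > ip) {
    span <- ip:id
    ref[span] <- d[ip] + (d[id] - d[ip]) * (span - ip) / (id - ip)
  }
  pds <- pmax(0, (1 - d / ref) * 100)
  if (all(pds > threshold)) {
    warning("no healthy shoulder found; using maximum diameter as reference",
            call. = FALSE)
    ref <- rep(max(d), n)
    pds <- pmax(0, (1 - d / ref) * 100)
  }
  labels <- ifelse(pds > threshold, "stenotic", "normal")
  structure(list(percent_ds = pds, reference_diameter = ref, labels = labels,
                 throat = imin, shoulders = c(proximal = ip, distal = id),
                 threshold = threshold, arclength = arclength),
            class = "sws_stenosis_profile")
}
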