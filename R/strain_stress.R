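# Membrane strain and stress of the superficial wall. The wall is treated as
# an incompressible, isotropic, hyperelastic Mooney-Rivlin membrane in plane
# stress (sigma3 = 0): strains come from in-plane element stretch ratios of
# the structured mesh, the through-thickness stretch follows from
# incompressibility (lambda3 = 1/(lambda1*lambda2)), and Cauchy stresses from
# W = C1*(I1bar - 3) + C2*(I2bar - 3) over the invariants of the unimodular
# left Cauchy-Green tensor.

#' Mooney-Rivlin material model for one tissue class
#'
#' @param c1,c2 material constants in kPa (`c1 > 0`, `c2 >= 0`).
#' @param tissue_class one of `"normal"`, `"fibrous"`, `"calcified"`,
#'   `"lipid_rich"`.
#' @return object of class `sws_material`.
#' @export
material_model <- function(c1, c2, tissue_class = "normal") {
  tissue_class <- match.arg(tissue_class,
                            c("normal", "fibrous", "calcified", "lipid_rich"))
  if (!is.finite(c1) || c1 <= 0) stop("c1 must be > 0 (kPa)", call. = FALSE)
  if (!is.finite(c2) || c2 < 0) stop("c2 must be >= 0 (kPa)", call. = FALSE)
  structure(list(c1 = c1, c2 = c2, tissue_class = tissue_class),
            class = "sws_material")
}

#' Default material table
#'
#' Placeholder constants, overridable everywhere they are consumed: normal
#' arterial wall C1 = 18.9 kPa, C2 = 2.75 kPa; fibrous plaque 2x, calcified
#' 10x, and lipid-rich 0.5x the normal constants. Analyses shipped with the
#' package depend on these only through ratios and orderings, never through
#' absolute magnitudes.
#'
#' @return named list of `sws_material` objects.
#' @export
default_materials <- function() {
  list(normal     = material_model(18.9, 2.75, "normal"),
       fibrous    = material_model(2 * 18.9, 2 * 2.75, "fibrous"),
       calcified  = material_model(10 * 18.9, 10 * 2.75, "calcified"),
       lipid_rich = material_model(0.5 * 18.9, 0.5 * 2.75, "lipid_rich"))
}

#' Mooney-Rivlin strain-energy density at an incompressible membrane state
#'
#' With `lambda3 = 1/(lambda1*lambda2)` the unimodular invariants equal the
#' plain invariants, so
#' `W = C1*(l1^2 + l2^2 + l3^2 - 3) + C2*(l1^-2 + l2^-2 + l3^-2 - 3)`.
#'
#' @param lambda1,lambda2 in-plane principal stretches (vectorized).
#' @param material an `sws_material`.
#' @return energy density in kPa.
#' @export
mooney_rivlin_energy <- function(lambda1, lambda2, material) {
  l3sq <- 1 / (lambda1 * lambda2)^2
  material$c1 * (lambda1^2 + lambda2^2 + l3sq - 3) +
    material$c2 * (1 / lambda1^2 + 1 / lambda2^2 + 1 / l3sq - 3)
}

#' In-plane deformation gradient of a quadrilateral membrane element
#'
#' The four edge vectors of the reference and deformed quadrilateral are
#' expressed in their respective in-plane orthonormal bases (first axis along
#' the mean circumferential edge, second axis the in-plane orthogonal
#' complement of the mean axial edge); `F` is the least-squares 2x2 linear map
#' sending the reference edge set to the deformed edge set.
#'
#' @param ref_element,def_element 4 x 3 matrices of node coordinates ordered
#'   `(i,j), (i,j+1), (i+1,j), (i+1,j+1)`.
#' @return 2 x 2 matrix `F` with `det(F) > 0`.
#' @export
element_deformation_gradient <- function(ref_element, def_element) {
  e2 <- function(q) {
    q <- as.matrix(q)
    ec1 <- q[2L, ] - q[1L, ]; ec2 <- q[4L, ] - q[3L, ]
    ea1 <- q[3L, ] - q[1L, ]; ea2 <- q[4L, ] - q[2L, ]
    u <- ec1 + ec2
    nu <- sqrt(sum(u^2))
    if (nu == 0) stop("degenerate quad element", call. = FALSE)
    u <- u / nu
    w <- ea1 + ea2
    v <- w - sum(w * u) * u
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("degenerate quad element", call. = FALSE)
    v <- v / nv
    E <- rbind(ec1, ec2, ea1, ea2)
    t(cbind(E %*% u, E %*% v))  # 2 x 4 edge coordinates
  }
  A <- e2(ref_element)
  B <- e2(def_element)
  F <- (B %*% t(A)) %*% solve(A %*% t(A))
  if (det(F) <= 0)
    stop("inverted element: deformation gradient has non-positive determinant",
         call. = FALSE)
  unname(F)
}

# Edge vectors of every quad element of an L x C x 3 node grid, projected
# onto the element's in-plane orthonormal basis. Internal workhorse shared by
# strain computation and the matching-energy evaluations (which cache the
# reference side).
grid_edge_coords <- function(nodes) {
  dims <- dim(nodes)
  L <- dims[1L]; C <- dims[2L]
  jp <- c(2:C, 1L)  # circumferential wrap
  a <- nodes[-L, , , drop = FALSE]            # (i, j)
  b <- nodes[-L, jp, , drop = FALSE]          # (i, j+1)
  cc <- nodes[-1L, , , drop = FALSE]          # (i+1, j)
  d <- nodes[-1L, jp, , drop = FALSE]         # (i+1, j+1)
  ec1 <- b - a; ec2 <- d - cc; ea1 <- cc - a; ea2 <- d - b
  u <- ec1 + ec2
  nu <- sqrt(u[, , 1L]^2 + u[, , 2L]^2 + u[, , 3L]^2)
  for (k in 1:3) u[, , k] <- u[, , k] / nu
  w <- ea1 + ea2
  wu <- w[, , 1L] * u[, , 1L] + w[, , 2L] * u[, , 2L] + w[, , 3L] * u[, , 3L]
  v <- w
  for (k in 1:3) v[, , k] <- w[, , k] - wu * u[, , k]
  nv <- sqrt(v[, , 1L]^2 + v[, , 2L]^2 + v[, , 3L]^2)
  for (k in 1:3) v[, , k] <- v[, , k] / nv
  pr <- function(e) {
    list(x = e[, , 1L] * u[, , 1L] + e[, , 2L] * u[, , 2L] + e[, , 3L] * u[, , 3L],
         y = e[, , 1L] * v[, , 1L] + e[, , 2L] * v[, , 2L] + e[, , 3L] * v[, , 3L])
  }
  list(pr(ec1), pr(ec2), pr(ea1), pr(ea2))
}

# Vectorized per-element deformation gradients between two L x C x 3 node
# grids. Returns list of (L-1) x C matrices F11, F12, F21, F22 and reference
# areas. Pre-projected edge coordinates may be supplied to avoid recomputation.
grid_deformation_gradients <- function(nodes_ref, nodes_def,
                                       A = NULL, B = NULL) {
  if (is.null(A)) A <- grid_edge_coords(nodes_ref)
  if (is.null(B)) B <- grid_edge_coords(nodes_def)
  a11 <- a12 <- a22 <- 0
  b11 <- b12 <- b21 <- b22 <- 0
  for (k in 1:4) {
    ax <- A[[k]]$x; ay <- A[[k]]$y
    bx <- B[[k]]$x; by <- B[[k]]$y
    a11 <- a11 + ax * ax; a12 <- a12 + ax * ay; a22 <- a22 + ay * ay
    b11 <- b11 + bx * ax; b12 <- b12 + bx * ay
    b21 <- b21 + by * ax; b22 <- b22 + by * ay
  }
  deta <- a11 * a22 - a12 * a12
  F11 <- (b11 * a22 - b12 * a12) / deta
  F12 <- (b12 * a11 - b11 * a12) / deta
  F21 <- (b21 * a22 - b22 * a12) / deta
  F22 <- (b22 * a11 - b21 * a12) / deta
  # reference element area (planar shoelace on projected corners a,b,d,c)
  bx <- A[[1L]]$x; by <- A[[1L]]$y                   # b - a
  cx <- A[[3L]]$x; cy <- A[[3L]]$y                   # c - a
  dx <- bx + A[[4L]]$x; dy <- by + A[[4L]]$y         # d - a = (b-a) + (d-b)
  area <- 0.5 * abs(bx * dy - by * dx) + 0.5 * abs(dx * cy - dy * cx)
  list(F11 = F11, F12 = F12, F21 = F21, F22 = F22, area = area)
}

# Compose two per-element 2x2 gradient lists: F_total = F_b %*% F_a
compose_gradients <- function(Fa, Fb) {
  list(F11 = Fb$F11 * Fa$F11 + Fb$F12 * Fa$F21,
       F12 = Fb$F11 * Fa$F12 + Fb$F12 * Fa$F22,
       F21 = Fb$F21 * Fa$F11 + Fb$F22 * Fa$F21,
       F22 = Fb$F21 * Fa$F12 + Fb$F22 * Fa$F22,
       area = Fa$area)
}

# Principal stretches (singular values) of per-element 2x2 gradients.
gradient_stretches <- function(Fg) {
  c11 <- Fg$F11^2 + Fg$F21^2
  c12 <- Fg$F11 * Fg$F12 + Fg$F21 * Fg$F22
  c22 <- Fg$F12^2 + Fg$F22^2
  tr <- c11 + c22
  disc <- sqrt(pmax((c11 - c22)^2 + 4 * c12^2, 0))
  mu1 <- 0.5 * (tr + disc)
  mu2 <- 0.5 * (tr - disc)
  detF <- Fg$F11 * Fg$F22 - Fg$F12 * Fg$F21
  if (any(detF <= 0))
    stop("inverted element: deformation gradient has non-positive determinant",
         call. = FALSE)
  l1 <- sqrt(pmax(mu1, 0))
  l2 <- detF / l1   # exact product identity keeps l1*l2 = det(F)
  list(lambda1 = l1, lambda2 = l2, lambda3 = 1 / (l1 * l2))
}

#' Principal stretches of an in-plane deformation gradient
#'
#' `lambda1 >= lambda2` are the singular values of `F`; the through-thickness
#' stretch follows from incompressibility, `lambda3 = 1/(lambda1*lambda2)`.
#'
#' @param F 2 x 2 deformation gradient with `det(F) > 0`.
#' @return numeric triple `(lambda1, lambda2, lambda3)`.
#' @export
principal_stretches <- function(F) {
  if (det(F) <= 0) stop("det(F) must be > 0", call. = FALSE)
  sv <- svd(F)$d
  c(lambda1 = sv[1L], lambda2 = sv[2L], lambda3 = 1 / (sv[1L] * sv[2L]))
}

#' Plane-stress incompressible Mooney-Rivlin principal Cauchy stresses
#'
#' With the hydrostatic pressure eliminated through `sigma3 = 0`:
#' `sigma_k = 2*C1*(lambda_k^2 - lambda3^2) - 2*C2*(lambda_k^-2 - lambda3^-2)`.
#'
#' @param stretches numeric triple `(lambda1, lambda2, lambda3)` with
#'   `lambda1*lambda2*lambda3 = 1`, or a list of equal-length vectors
#'   `lambda1`, `lambda2`, `lambda3`.
#' @param material an `sws_material`.
#' @return list with vectors `sigma1`, `sigma2` in kPa.
#' @export
mooney_rivlin_cauchy <- function(stretches, material) {
  if (is.numeric(stretches))
    stretches <- list(lambda1 = stretches[[1L]], lambda2 = stretches[[2L]],
                      lambda3 = stretches[[3L]])
  l1 <- stretches$lambda1; l2 <- stretches$lambda2; l3 <- stretches$lambda3
  s <- function(lk) 2 * material$c1 * (lk^2 - l3^2) -
    2 * material$c2 * (1 / lk^2 - 1 / l3^2)
  list(sigma1 = s(l1), sigma2 = s(l2))
}

#' Von Mises equivalent stress under plane stress
#'
#' @param sigma1,sigma2 in-plane principal Cauchy stresses, kPa (vectorized).
#' @return `sqrt(sigma1^2 - sigma1*sigma2 + sigma2^2)` in kPa.
#' @export
von_mises <- function(sigma1, sigma2) {
  sqrt(sigma1^2 - sigma1 * sigma2 + sigma2^2)
}

#' Strain fields over a propagated cardiac cycle
#'
#' In `"incremental"` mode the deformation gradient of each frame is taken
#' against the previous frame's matched configuration (the element
#' length-ratio step). In `"cumulative"` mode (the default, used for reported
#' maximum principal strain) the per-step gradients are composed from the
#' diastasis reference: `F_total(k) = F_k ... F_1`.
#'
#' @param propagation an `sws_propagation` from [propagate_cycle()].
#' @param mode `"cumulative"` or `"incremental"`.
#' @return list of per-frame strain fields (class `sws_strain_field`), one per
#'   frame of the sequence; the diastasis entry is identically zero. Each has
#'   (L-1) x C matrices `lambda1`, `lambda2`, `lambda3`,
#'   `max_principal_strain` (= lambda1 - 1), `green1` and the element-mid
#'   arclength vector `element_arclength`.
#' @export
compute_strain_series <- function(propagation, mode = c("cumulative", "incremental")) {
  mode <- match.arg(mode)
  stopifnot(inherits(propagation, "sws_propagation"))
  grids <- propagation$grids
  K <- length(grids)
  s <- propagation$arclength
  mid_s <- 0.5 * (s[-1L] + s[-length(s)])
  zero <- grid_deformation_gradients(grids[[1L]], grids[[1L]])
  out <- vector("list", K)
  acc <- NULL
  for (k in seq_len(K)) {
    if (k == 1L) {
      Fg <- zero
    } else {
      step <- grid_deformation_gradients(grids[[k - 1L]], grids[[k]])
      Fg <- if (mode == "incremental") step else {
        acc <- if (is.null(acc)) step else compose_gradients(acc, step)
        acc
      }
    }
    st <- gradient_stretches(Fg)
    out[[k]] <- structure(
      list(F = Fg, lambda1 = st$lambda1, lambda2 = st$lambda2,
           lambda3 = st$lambda3,
           max_principal_strain = st$lambda1 - 1,
           green1 = 0.5 * (st$lambda1^2 - 1),
           mode = mode, element_arclength = mid_s,
           phase = propagation$phases[k],
           time_index = propagation$time_index[k]),
      class = "sws_strain_field")
  }
  out
}

#' Stress fields from strain fields with lesion-aware material assignment
#'
#' Each element takes the material of its segment class: elements on stenotic
#' rings (percent diameter stenosis above the profile threshold) receive the
#' lesion composition's material, all others the normal wall material.
#'
#' @param strain_series list of `sws_strain_field` from
#'   [compute_strain_series()].
#' @param profile an `sws_stenosis_profile` at the mesh ring resolution
#'   (length-L `percent_ds`).
#' @param materials named list of `sws_material` containing `"normal"` and the
#'   lesion class named by `lesion_class`.
#' @param lesion_class tissue class used for stenotic elements; defaults to
#'   the single non-normal entry of `materials`.
#' @return list of per-frame stress fields (class `sws_stress_field`) with
#'   (L-1) x C matrices `sigma1`, `sigma2`, `von_mises`, the element material
#'   class matrix `material`, and `element_arclength`.
#' @export
compute_stress_series <- function(strain_series, profile, materials = default_materials(),
                                  lesion_class = NULL) {
  stopifnot(inherits(profile, "sws_stenosis_profile"))
  if (is.null(lesion_class)) {
    cand <- setdiff(names(materials), "normal")
    lesion_class <- if (length(cand)) cand[[1L]] else "normal"
  }
  if (!"normal" %in% names(materials))
    stop("materials must contain a 'normal' entry", call. = FALSE)
  if (!lesion_class %in% names(materials))
    stop(sprintf("materials is missing the lesion class '%s'", lesion_class),
         call. = FALSE)
  lab <- profile$labels
  L <- length(lab)
  # element is stenotic when either bounding ring is
  elem_sten <- (lab[-L] == "stenotic") | (lab[-1L] == "stenotic")
  lapply(strain_series, function(sf) {
    d <- dim(sf$lambda1)
    sten <- matrix(elem_sten, d[1L], d[2L])
    sig1 <- sig2 <- matrix(0, d[1L], d[2L])
    for (cls in c("normal", lesion_class)) {
      sel <- if (cls == "normal") !sten else sten
      if (!any(sel)) next
      st <- list(lambda1 = sf$lambda1[sel], lambda2 = sf$lambda2[sel],
                 lambda3 = sf$lambda3[sel])
      sg <- mooney_rivlin_cauchy(st, materials[[cls]])
      sig1[sel] <- sg$sigma1
      sig2[sel] <- sg$sigma2
    }
    structure(list(sigma1 = sig1, sigma2 = sig2,
                   von_mises = von_mises(sig1, sig2),
                   material = ifelse(sten, lesion_class, "normal"),
                   element_arclength = sf$element_arclength,
                   phase = sf$phase, time_index = sf$time_index),
              class = "sws_stress_field")
  })
}

#' Pulse stress between end-systole and end-diastole
#'
#' Per-element absolute difference of the von Mises stress at the two states;
#' a candidate fatigue/fracture localizer. The peak element and its arclength
#' position from the proximal (ostial) end are reported.
#'
#' @param stress_es,stress_ed `sws_stress_field`s on the same mesh topology
#'   (conventionally end-systole and end-diastole).
#' @return list with matrix `pulse` (kPa), `max` (kPa), `argmax`
#'   (`c(ring_element, column)`), and `arclength_mm` of the peak element's
#'   mid-position from the ostial end.
#' @export
pulse_stress <- function(stress_es, stress_ed) {
  if (!identical(dim(stress_es$von_mises), dim(stress_ed$von_mises)))
    stop("stress fields have mismatched mesh topology", call. = FALSE)
  p <- abs(stress_es$von_mises - stress_ed$von_mises)
  am <- which(p == max(p), arr.ind = TRUE)[1L, ]
  list(pulse = p, max = max(p),
       argmax = c(ring_element = unname(am[1L]), column = unname(am[2L])),
       arclength_mm = stress_es$element_arclength[am[1L]])
}

#' Cycle summary: per-segment time averages and peak stress location
#'
#' Time-averages the element-wise maximum principal strain and von Mises
#' stress over all frames of the cycle, reports the mean of each over the
#' normal and stenotic segment elements, and classifies the location of the
#' cycle-maximum von Mises stress as proximal shoulder, throat, distal
#' shoulder or normal segment. Shoulders are the stenotic rings proximal or
#' distal to the minimum-diameter (throat) ring.
#'
#' @param strain_series,stress_series outputs of [compute_strain_series()] and
#'   [compute_stress_series()].
#' @param profile the `sws_stenosis_profile` used for material assignment.
#' @return list with `strain_normal`, `strain_stenotic`, `stress_normal`,
#'   `stress_stenotic` (time-averaged segment means), `peak_location`
#'   (`"proximal_shoulder"`, `"throat"`, `"distal_shoulder"` or `"normal"`),
#'   `peak_stress` (kPa), `peak_arclength_mm`, and `lesion_max_von_mises`
#'   (cycle maximum over stenotic elements, kPa; `NA` without a lesion).
#' @export
summarize_fields <- function(strain_series, stress_series, profile) {
  stopifnot(inherits(profile, "sws_stenosis_profile"))
  lab <- profile$labels
  L <- length(lab)
  elem_sten <- (lab[-L] == "stenotic") | (lab[-1L] == "stenotic")
  d <- dim(strain_series[[1L]]$lambda1)
  sten <- matrix(elem_sten, d[1L], d[2L])

  avg <- function(series, what) Reduce(`+`, lapply(series, `[[`, what)) / length(series)
  mean_strain <- avg(strain_series, "max_principal_strain")
  mean_stress <- avg(stress_series, "von_mises")

  cyc_max <- Reduce(pmax, lapply(stress_series, `[[`, "von_mises"))
  am <- which(cyc_max == max(cyc_max), arr.ind = TRUE)[1L, ]
  peak_elem_row <- unname(am[1L])
  # the peak element's ring: the more diseased of its two bounding rings
  ring <- if (profile$percent_ds[peak_elem_row] >= profile$percent_ds[peak_elem_row + 1L])
    peak_elem_row else peak_elem_row + 1L
  loc <- if (!any(lab == "stenotic") || lab[ring] != "stenotic") "normal"
  else if (ring == profile$throat) "throat"
  else if (ring < profile$throat) "proximal_shoulder"
  else "distal_shoulder"

  list(strain_normal = mean(mean_strain[!sten]),
       strain_stenotic = if (any(sten)) mean(mean_strain[sten]) else NA_real_,
       stress_normal = mean(mean_stress[!sten]),
       stress_stenotic = if (any(sten)) mean(mean_stress[sten]) else NA_real_,
       peak_location = loc,
       peak_stress = max(cyc_max),
       peak_arclength_mm = stress_series[[1L]]$element_arclength[peak_elem_row],
       lesion_max_von_mises = if (any(sten)) max(cyc_max[sten]) else NA_real_)
}
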