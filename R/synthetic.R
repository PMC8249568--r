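# Synthetic in-silico stenosis models and forward-simulated cardiac-cycle
# motion with known ground truth. The generator emulates idealized stenotic
# human coronary vessels: 3 mm nominal lumen, 50 mm length, a 10 mm
# concentric mid-vessel lesion with 50% diameter stenosis, plaque burdens of
# 50.9/62.6/69.1 percent volume across calcified/fibrous/lipid-rich
# compositions and negative/none/positive arterial remodeling, and cyclic
# motion combining 10-15% diameter pulsation with axial stretch, bending and
# rigid-body motion.

#' Plaque specification for an in-silico stenosis model
#'
#' @param composition `"calcified"`, `"fibrous"` or `"lipid_rich"`.
#' @param burden_target plaque burden as a fraction of the external-elastic-
#'   membrane volume over the lesion, in (0, 0.95). Canonical levels are
#'   0.509, 0.626 and 0.691.
#' @param remodeling `"negative"`, `"none"` or `"positive"` lesion-level
#'   remodeling of the external elastic membrane.
#' @return object of class `sws_plaque_spec`.
#' @export
plaque_spec <- function(composition = c("fibrous", "calcified", "lipid_rich"),
                        burden_target = 0.509,
                        remodeling = c("none", "negative", "positive")) {
  composition <- match.arg(composition)
  remodeling <- match.arg(remodeling)
  if (!is.finite(burden_target) || burden_target <= 0 || burden_target >= 0.95)
    stop("burden_target must lie in (0, 0.95)", call. = FALSE)
  structure(list(composition = composition, burden_target = burden_target,
                 remodeling = remodeling),
            class = "sws_plaque_spec")
}

# cosine taper bump: 1 at the lesion mid-point, 0 at and beyond the edges
lesion_bump <- function(s, s_mid, lesion_length) {
  ifelse(abs(s - s_mid) <= lesion_length / 2,
         0.5 * (1 + cos(2 * pi * (s - s_mid) / lesion_length)), 0)
}

#' Construct an idealized concentric stenosis model
#'
#' The lumen is a straight tube of nominal radius with a cosine-tapered
#' concentric lesion reaching `(1 - ds/100)` of the nominal radius at the
#' lesion mid-point. The external elastic membrane (EEM) equals the nominal
#' lumen radius plus the normal wall thickness outside the lesion; inside, it
#' is the reference EEM scaled by a remodeling multiplier applied with the
#' same cosine taper (negative < 1, none = 1, positive > 1). The normal wall
#' thickness is then solved so that the achieved plaque burden over the
#' lesion matches `spec$burden_target` (within 5e-3); an unattainable target
#' raises an error naming the feasible bound.
#'
#' @param spec an `sws_plaque_spec`.
#' @param lumen_diameter nominal lumen diameter, mm (default 3).
#' @param length vessel length, mm (default 50).
#' @param lesion_length lesion length, mm (default 10, centred).
#' @param ds percent diameter stenosis at the lesion mid-point, in (0, 95)
#'   (default 50).
#' @param n_rings number of centerline rings (default 101).
#' @param wall_thickness normal wall thickness in mm, or `NULL` (default) to
#'   solve it for the burden target.
#' @param remodeling_multiplier named multipliers of the lesion EEM relative
#'   to the reference EEM per remodeling class.
#' @return object of class `sws_insilico_vessel`: list with `lumen` (a
#'   diastasis `sws_vessel_frame`), `eem_radius`, `lesion_span` (ring index
#'   range), `wall_thickness`, `spec`, and the geometry arguments.
#' @export
make_stenosis_model <- function(spec, lumen_diameter = 3, length = 50,
                                lesion_length = 10, ds = 50, n_rings = 101L,
                                wall_thickness = NULL,
                                remodeling_multiplier = c(negative = 0.95,
                                                          none = 1.00,
                                                          positive = 1.10)) {
  stopifnot(inherits(spec, "sws_plaque_spec"))
  if (ds < 0 || ds >= 95) stop("ds must lie in [0, 95)", call. = FALSE)
  if (lesion_length >= length)
    stop("lesion_length must be smaller than length", call. = FALSE)
  r0 <- lumen_diameter / 2
  s <- seq(0, length, length.out = n_rings)
  s_mid <- length / 2
  bump <- lesion_bump(s, s_mid, lesion_length)
  r_lum <- r0 * (1 - (ds / 100) * bump)
  span <- which(abs(s - s_mid) <= lesion_length / 2)
  if (!length(span)) stop("undefined burden: empty lesion span", call. = FALSE)
  m <- remodeling_multiplier[[spec$remodeling]]

  eem_for <- function(t) (r0 + t) * (1 + (m - 1) * bump)
  burden_for <- function(t) {
    v <- list(lumen = r_lum, eem = eem_for(t))
    frustum_burden(v$lumen[span], v$eem[span], s[span])
  }
  if (is.null(wall_thickness)) {
    lo <- 0.02; hi <- 5
    b_lo <- burden_for(lo); b_hi <- burden_for(hi)
    tgt <- spec$burden_target
    if (tgt < b_lo || tgt > b_hi)
      stop(sprintf(paste0("burden_target %.3f infeasible for remodeling '%s': ",
                          "achievable range is [%.3f, %.3f] for wall thickness ",
                          "in [%.2f, %.2f] mm"),
                   tgt, spec$remodeling, b_lo, b_hi, lo, hi), call. = FALSE)
    wall_thickness <- stats::uniroot(function(t) burden_for(t) - tgt,
                                     c(lo, hi), tol = 1e-10)$root
  }
  eem <- eem_for(wall_thickness)
  if (any(eem <= r_lum))
    stop("invalid geometry: EEM radius must exceed the lumen radius everywhere",
         call. = FALSE)
  lumen <- vessel_frame(cbind(0, 0, s), r_lum, phase = "diastasis",
                        time_index = 0L)
  structure(list(lumen = lumen, eem_radius = eem, lesion_span = span,
                 wall_thickness = wall_thickness, spec = spec,
                 lumen_diameter = lumen_diameter, length = length,
                 lesion_length = lesion_length, ds = ds,
                 remodeling_multiplier = m),
            class = "sws_insilico_vessel")
}

# (EEM - lumen)/EEM volume by exact conical-frustum integration of pi*r^2 ds
frustum_burden <- function(r_lum, r_eem, s) {
  vol <- function(r) {
    h <- diff(s)
    sum(pi / 3 * h * (r[-length(r)]^2 + r[-length(r)] * r[-1L] + r[-1L]^2))
  }
  ve <- vol(r_eem)
  (ve - vol(r_lum)) / ve
}

#' Plaque burden of an in-silico vessel
#'
#' `(EEM volume - lumen volume) / EEM volume` over the lesion span, with
#' volumes by conical-frustum integration along the centerline.
#'
#' @param vessel an `sws_insilico_vessel`.
#' @return burden fraction in `[0, 1)`.
#' @export
plaque_burden <- function(vessel) {
  stopifnot(inherits(vessel, "sws_insilico_vessel"))
  span <- vessel$lesion_span
  if (!length(span)) stop("undefined burden: empty lesion span", call. = FALSE)
  s <- vessel$lumen$centerline$arclength
  frustum_burden(vessel$lumen$radius[span], vessel$eem_radius[span], s[span])
}

#' Cardiac-cycle motion specification
#'
#' All components are applied with a per-phase scalar weight; diastasis has
#' weight 0 by construction (it is the zero-deformation reference state).
#' Inside the lesion the radial pulsation is multiplied by
#' `stiffness_attenuation` (tapered with the lesion profile), emulating the
#' reduced distensibility of diseased wall; defaults per composition are
#' calcified 0.2, fibrous 0.5 and lipid-rich 0.8 of the normal pulsation.
#'
#' @param diameter_pulsation peak fractional diameter increase at full weight
#'   (default 0.12; physiological pulsation is ~0.10-0.15).
#' @param axial_stretch peak fractional length change about the proximal end.
#' @param bending_amplitude peak added centerline curvature, 1/mm.
#' @param bending_center_mm arclength of the bending apex (default: vessel
#'   mid-length, set at generation time when `NULL`).
#' @param bending_sigma_mm Gaussian width of the bending deflection, mm.
#' @param bending_direction angle of the transverse bending direction in the
#'   cross-section plane, rad.
#' @param rigid_translation length-3 peak rigid translation, mm.
#' @param rigid_rotation peak rigid rotation angle, rad.
#' @param rotation_axis length-3 rotation axis (normalized internally).
#' @param stiffness_attenuation lesion pulsation multiplier in `[0, 1]`.
#' @param phase_weights named per-phase weights in `[-1, 1]`; must contain
#'   `diastasis = 0`.
#' @return object of class `sws_motion_spec`.
#' @export
motion_spec <- function(diameter_pulsation = 0.12,
                        axial_stretch = 0.03,
                        bending_amplitude = 0.008,
                        bending_center_mm = NULL,
                        bending_sigma_mm = 8,
                        bending_direction = 0,
                        rigid_translation = c(1, 1, 1),
                        rigid_rotation = 0.02,
                        rotation_axis = c(0, 1, 0),
                        stiffness_attenuation = 0.5,
                        phase_weights = default_phase_weights()) {
  if (is.na(phase_weights["diastasis"]) || phase_weights[["diastasis"]] != 0)
    stop("phase_weights must assign weight 0 to diastasis", call. = FALSE)
  if (stiffness_attenuation < 0 || stiffness_attenuation > 1)
    stop("stiffness_attenuation must lie in [0, 1]", call. = FALSE)
  structure(list(diameter_pulsation = diameter_pulsation,
                 axial_stretch = axial_stretch,
                 bending_amplitude = bending_amplitude,
                 bending_center_mm = bending_center_mm,
                 bending_sigma_mm = bending_sigma_mm,
                 bending_direction = bending_direction,
                 rigid_translation = rigid_translation,
                 rigid_rotation = rigid_rotation,
                 rotation_axis = rotation_axis / sqrt(sum(rotation_axis^2)),
                 stiffness_attenuation = stiffness_attenuation,
                 phase_weights = phase_weights),
            class = "sws_motion_spec")
}

#' Default raised-cosine phase weights over one cardiac cycle
#'
#' Zero at diastasis, extremum at end-systole, smoothly returning toward the
#' next diastasis.
#'
#' @return named numeric vector over the five canonical phases.
#' @export
default_phase_weights <- function() {
  # sin^2 waveform over cycle fraction, peaking at end-systole (tau = 0.6)
  tau <- c(diastasis = 0, end_diastole = 0.2, early_systole = 0.4,
           end_systole = 0.6, early_diastole = 0.8)
  w <- sin(pi * tau / 1.2)^2 / sin(pi * 0.6 / 1.2)^2
  w["diastasis"] <- 0
  w
}

#' Stiffness attenuation defaults per plaque composition
#'
#' @param composition plaque composition class.
#' @return lesion pulsation multiplier: softer plaque pulsates more.
#' @export
attenuation_for <- function(composition) {
  c(calcified = 0.2, fibrous = 0.5, lipid_rich = 0.8)[[composition]]
}

rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(angle); st <- sin(angle)
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L, 3L)
  diag(3) + st * K + (1 - ct) * (K %*% K)
}

#' Forward-simulate a cardiac motion sequence with known ground truth
#'
#' Starting from the diastasis structured mesh of the vessel, each phase
#' applies with its weight: radial scaling (attenuated inside the lesion),
#' axial stretch about the proximal end, a smooth Gaussian transverse bending
#' of the centerline, and rigid-body rotation plus translation. True per-node
#' displacement grids (cumulative from diastasis) are stored as ground truth.
#' The sequence is cyclic: composing the inter-frame ground-truth motions
#' around the cycle returns every node to its diastasis position exactly.
#'
#' @param vessel an `sws_insilico_vessel`.
#' @param motion an `sws_motion_spec`.
#' @param phases ordered phase labels starting at `"diastasis"`.
#' @param seed integer; kept with the sequence for provenance (the generator
#'   itself is deterministic given `vessel` and `motion`).
#' @param L,C mesh dimensions shared by every frame of the sequence.
#' @return object of class `sws_cardiac_sequence`: list with `frames`
#'   (list of `sws_vessel_frame`), `L`, `C`, `ground_truth` (list with
#'   per-frame `node_grids` and cumulative `displacements`), `motion`,
#'   `vessel`, `seed`.
#' @export
generate_cardiac_sequence <- function(vessel, motion = motion_spec(),
                                      phases = names(default_phase_weights()),
                                      seed = 0L, L = 101L, C = 32L) {
  stopifnot(inherits(vessel, "sws_insilico_vessel"),
            inherits(motion, "sws_motion_spec"))
  if (phases[1L] != "diastasis")
    stop("phases must start at diastasis", call. = FALSE)
  w <- motion$phase_weights[phases]
  if (anyNA(w)) stop("phase_weights must cover every requested phase", call. = FALSE)

  mesh0 <- build_structured_mesh(vessel$lumen, L = L, C = C)
  s <- mesh0$arclength
  ctr0 <- mesh_centerline(mesh0)
  s_mid <- vessel$length / 2
  att <- 1 - (1 - motion$stiffness_attenuation) *
    lesion_bump(s, s_mid, vessel$lesion_length)
  b_ctr <- if (is.null(motion$bending_center_mm)) s_mid else motion$bending_center_mm
  defl_shape <- motion$bending_amplitude * motion$bending_sigma_mm^2 *
    exp(-(s - b_ctr)^2 / (2 * motion$bending_sigma_mm^2))
  b_dir <- c(cos(motion$bending_direction), sin(motion$bending_direction), 0)
  centroid <- colMeans(ctr0)

  frames <- vector("list", length(phases))
  grids <- vector("list", length(phases))
  for (k in seq_along(phases)) {
    wk <- w[[k]]
    rad_scale <- 1 + wk * motion$diameter_pulsation * att
    # self-intersection guard: bent tube must keep radius below 1/curvature
    max_kappa <- abs(wk) * motion$bending_amplitude
    if (max(mesh0$radius * rad_scale) * max_kappa >= 1)
      stop(sprintf("motion produces a self-intersecting tube at frame %d (%s)",
                   k, phases[k]), call. = FALSE)
    nodes <- mesh0$nodes
    for (d in 1:3) {
      nodes[, , d] <- ctr0[, d] + rad_scale * (nodes[, , d] - ctr0[, d])
    }
    # axial stretch about the proximal end (straight synthetic axis along z)
    nodes[, , 3L] <- ctr0[1L, 3L] + (1 + wk * motion$axial_stretch) *
      (nodes[, , 3L] - ctr0[1L, 3L])
    ctr_k <- ctr0
    ctr_k[, 3L] <- ctr0[1L, 3L] + (1 + wk * motion$axial_stretch) *
      (ctr0[, 3L] - ctr0[1L, 3L])
    # bending: translate each ring along the deflection and tilt it so the
    # cross-section stays normal to the bent axis (material sections follow
    # the curve, as a tethered artery does)
    if (wk * motion$bending_amplitude != 0) {
      dshape <- -defl_shape * (s - b_ctr) / motion$bending_sigma_mm^2
      for (i in seq_len(dim(nodes)[1L])) {
        tnew <- c(0, 0, 1) + wk * dshape[i] * b_dir
        tnew <- tnew / sqrt(sum(tnew^2))
        ax <- cross3(c(0, 0, 1), tnew)
        sa <- sqrt(sum(ax^2))
        R <- if (sa < 1e-300) diag(3) else
          rotation_matrix(ax / sa, asin(min(sa, 1)))
        ring <- cbind(nodes[i, , 1L] - ctr_k[i, 1L],
                      nodes[i, , 2L] - ctr_k[i, 2L],
                      nodes[i, , 3L] - ctr_k[i, 3L]) %*% t(R)
        for (d in 1:3)
          nodes[i, , d] <- ctr_k[i, d] + wk * defl_shape[i] * b_dir[d] + ring[, d]
      }
    }
    # rigid-body motion about the diastasis centroid
    R <- rotation_matrix(motion$rotation_axis, wk * motion$rigid_rotation)
    tr <- wk * motion$rigid_translation
    flat <- matrix(nodes, ncol = 3L)
    flat <- sweep(flat, 2L, centroid) %*% t(R)
    flat <- sweep(flat, 2L, centroid + tr, `+`)
    nodes <- array(flat, dim = dim(nodes))
    grids[[k]] <- nodes

    ctr_k <- apply(nodes, c(1L, 3L), mean)
    frames[[k]] <- vessel_frame(ctr_k, mesh0$radius * rad_scale,
                                phase = phases[k], time_index = k - 1L)
  }
  disp <- lapply(grids, function(g) g - grids[[1L]])
  structure(list(frames = frames, L = L, C = C,
                 ground_truth = list(node_grids = grids, displacements = disp),
                 motion = motion, vessel = vessel, seed = as.integer(seed)),
            class = "sws_cardiac_sequence")
}

# evaluate a function with a temporary RNG state derived from an explicit seed
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a reproducible cohort of synthetic cardiac sequences
#'
#' Plaque specifications cycle deterministically through the full
#' composition x burden x remodeling design (so all three compositions are
#' covered whenever `n >= 9`, and the full 27-cell design at `n >= 27`);
#' motion parameters are drawn from documented physiological ranges using a
#' single RNG stream initialized from `seed`.
#'
#' @param n number of sequences (>= 1).
#' @param seed integer seed; the same `(n, seed)` reproduces the cohort
#'   exactly.
#' @param L,C mesh dimensions for every sequence.
#' @param proximal_bias if `TRUE`, bending apices are drawn near the proximal
#'   lesion shoulder instead of uniformly over the mid-vessel.
#' @return list of `n` `sws_cardiac_sequence` objects.
#' @export
make_validation_cohort <- function(n, seed = 1L, L = 101L, C = 32L,
                                   proximal_bias = FALSE) {
  stopifnot(n >= 1)
  design <- expand.grid(composition = c("calcified", "fibrous", "lipid_rich"),
                        burden = c(0.509, 0.626, 0.691),
                        remodeling = c("negative", "none", "positive"),
                        stringsAsFactors = FALSE)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      row <- design[(i - 1L) %% nrow(design) + 1L, ]
      spec <- plaque_spec(row$composition, row$burden, row$remodeling)
      vessel <- make_stenosis_model(spec)
      prox_shoulder <- vessel$length / 2 - vessel$lesion_length / 2
      motion <- motion_spec(
        diameter_pulsation = stats::runif(1L, 0.10, 0.15),
        axial_stretch = stats::runif(1L, 0.02, 0.05),
        bending_amplitude = stats::runif(1L, 0.004, 0.012),
        bending_center_mm = if (proximal_bias)
          stats::runif(1L, prox_shoulder - 3, prox_shoulder + 3)
        else stats::runif(1L, 15, 35),
        bending_sigma_mm = stats::runif(1L, 6, 10),
        bending_direction = stats::runif(1L, 0, 2 * pi),
        rigid_translation = stats::runif(3L, -2, 2),
        rigid_rotation = stats::runif(1L, 0, 0.05),
        stiffness_attenuation = attenuation_for(row$composition))
      generate_cardiac_sequence(vessel, motion, seed = seed + i, L = L, C = C)
    })
  })
}
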