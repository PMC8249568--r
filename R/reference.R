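# Conventional force-based comparator: closed-form Laplace hoop stress and a
# quasi-static axisymmetric incompressible Mooney-Rivlin membrane solver that
# forward-simulates pressurized vessels ring by ring. Used to validate the
# inverse displacement-based pipeline end to end and to generate
# equilibrium-consistent synthetic motion with known stress ground truth.
# Pressures are kPa throughout (1 mmHg = 0.13332 kPa).

#' Laplace-law hoop stress of a thin-walled pressurized tube
#'
#' @param P transmural pressure, kPa.
#' @param r lumen radius, mm.
#' @param t wall thickness, mm (> 0).
#' @return circumferential (hoop) stress `P * r / t`, kPa.
#' @export
laplace_hoop_stress <- function(P, r, t) {
  if (any(t <= 0)) stop("invalid geometry: wall thickness must be > 0",
                        call. = FALSE)
  P * r / t
}

#' Convert mmHg to kPa
#'
#' @param mmHg pressure in mmHg.
#' @return pressure in kPa (1 mmHg = 0.13332 kPa).
#' @export
mmHg_to_kPa <- function(mmHg) 0.13332 * mmHg

# membrane equilibrium of one ring: find lambda_theta such that
# sigma_theta(lambda_theta, lambda_z) * t_def = P * r_def, with
# t_def = t_ref/(lambda_theta*lambda_z) and r_def = lambda_theta*r_ref.
ring_equilibrium <- function(P, r_ref, t_ref, material, lambda_z = 1,
                             lambda_max = 4) {
  g <- function(lt) {
    l3 <- 1 / (lt * lambda_z)
    sg <- mooney_rivlin_cauchy(list(lambda1 = lt, lambda2 = lambda_z,
                                    lambda3 = l3), material)$sigma1
    sg * t_ref * l3 - P * lt * r_ref
  }
  if (P == 0 && lambda_z == 1) return(list(lambda = 1, residual = 0))
  lo <- 1e-3
  if (g(lo) * g(lambda_max) > 0)
    stop(sprintf("no membrane equilibrium in stretch bracket (limit point?) at P = %.3g kPa",
                 P), call. = FALSE)
  root <- stats::uniroot(g, c(lo, lambda_max), tol = 1e-12)
  list(lambda = root$root, residual = abs(g(root$root)))
}

#' Axisymmetric membrane equilibrium of a pressurized in-silico vessel
#'
#' Per ring, solves the incompressible Mooney-Rivlin cylindrical membrane
#' equilibrium `P * r_def = sigma_theta(lambda_theta, lambda_z) * t_def` by
#' bracketed root-finding on the circumferential stretch, with the axial
#' stretch held fixed (coronary tethering) and the deformed thickness
#' `t_def = t_ref / (lambda_theta * lambda_z)` from incompressibility. The
#' reference (unloaded) geometry is the vessel's diastasis lumen; wall
#' thickness is EEM minus lumen radius. Rings labelled stenotic by the
#' vessel's diameter-stenosis profile take the plaque composition's material.
#'
#' @param vessel an `sws_insilico_vessel`.
#' @param load list with `pressure` (kPa, >= 0); see also
#'   [forward_pressurized_sequence()] for waveforms.
#' @param materials named list of `sws_material` covering `"normal"` and the
#'   vessel's composition.
#' @param lambda_z fixed axial stretch (default 1).
#' @param threshold percent-diameter-stenosis threshold for the material
#'   segmentation (default 20).
#' @return object of class `sws_equilibrium`: list with per-ring
#'   `deformed_radius` (mm), `hoop_stress` (kPa), `lambda_theta`, `residual`,
#'   and the per-ring `material` classes.
#' @export
solve_membrane_equilibrium <- function(vessel, load,
                                       materials = default_materials(),
                                       lambda_z = 1, threshold = 20) {
  stopifnot(inherits(vessel, "sws_insilico_vessel"))
  P <- load$pressure
  if (is.null(P) || !is.finite(P) || P < 0)
    stop("load$pressure must be a finite pressure >= 0 (kPa)", call. = FALSE)
  r_ref <- vessel$lumen$radius
  t_ref <- vessel$eem_radius - r_ref
  if (any(t_ref <= 0))
    stop("invalid geometry: wall thickness must be > 0 everywhere", call. = FALSE)
  prof <- compute_stenosis_profile(vessel$lumen, threshold = threshold)
  cls <- ifelse(prof$labels == "stenotic", vessel$spec$composition, "normal")
  if (!all(unique(cls) %in% names(materials)))
    stop("materials must cover the normal wall and the plaque composition",
         call. = FALSE)
  n <- length(r_ref)
  lam <- num <- res <- numeric(n)
  for (i in seq_len(n)) {
    eq <- tryCatch(ring_equilibrium(P, r_ref[i], t_ref[i], materials[[cls[i]]],
                                    lambda_z),
                   error = function(e)
                     stop(sprintf("ring %d: %s", i, conditionMessage(e)),
                          call. = FALSE))
    lam[i] <- eq$lambda
    res[i] <- eq$residual
  }
  l3 <- 1 / (lam * lambda_z)
  hoop <- vapply(seq_len(n), function(i)
    mooney_rivlin_cauchy(list(lambda1 = lam[i], lambda2 = lambda_z,
                              lambda3 = l3[i]),
                         materials[[cls[i]]])$sigma1, 0)
  structure(list(deformed_radius = lam * r_ref, hoop_stress = hoop,
                 lambda_theta = lam, residual = res, material = cls,
                 pressure = P, lambda_z = lambda_z),
            class = "sws_equilibrium")
}

#' Forward-simulate a pressurized cardiac sequence with stress ground truth
#'
#' Assembles per-phase membrane equilibria into a cardiac sequence whose
#' ground truth carries the forward hoop stresses and circumferential
#' stretches. The diastasis phase must carry zero transmural pressure: the
#' diastasis configuration is the stress-free reference of the inverse
#' pipeline, so forward stresses are expressed relative to it. When
#' `target_pulsation` is given, all non-diastasis pressures are scaled by a
#' common factor such that the peak-pressure fractional diameter change of
#' the normal mid-segment equals the target (physiological pulsation is
#' 0.10-0.15).
#'
#' @param vessel an `sws_insilico_vessel`.
#' @param waveform named per-phase pressures in kPa, containing
#'   `diastasis = 0`; default: [default_phase_weights()] scaled by 4 kPa
#'   (~30 mmHg pulse pressure).
#' @param materials named list of `sws_material`.
#' @param target_pulsation optional normal-segment peak fractional diameter
#'   change; scales the waveform.
#' @param lambda_z fixed axial stretch.
#' @param threshold percent-diameter-stenosis threshold for material
#'   segmentation.
#' @param L,C mesh dimensions recorded with the sequence.
#' @return an `sws_cardiac_sequence` whose `ground_truth` holds per-frame
#'   `hoop_stress` and `lambda_theta` (per centerline ring) and the scaled
#'   `waveform`.
#' @export
forward_pressurized_sequence <- function(vessel,
                                         waveform = 4 * default_phase_weights(),
                                         materials = default_materials(),
                                         target_pulsation = NULL,
                                         lambda_z = 1, threshold = 20,
                                         L = 101L, C = 32L) {
  stopifnot(inherits(vessel, "sws_insilico_vessel"))
  if (is.na(waveform["diastasis"]))
    stop("waveform must contain a diastasis entry", call. = FALSE)
  if (waveform[["diastasis"]] != 0)
    stop("diastasis transmural pressure must be 0: it is the stress-free reference",
         call. = FALSE)
  if (!is.null(target_pulsation)) {
    # scale pressures so the normal mid-segment pulsates by the target
    i_ref <- normal_reference_ring(vessel, threshold)
    r_ref <- vessel$lumen$radius[i_ref]
    t_ref <- vessel$eem_radius[i_ref] - r_ref
    pk <- max(waveform)
    f <- function(scale) tryCatch(
      ring_equilibrium(scale * pk, r_ref, t_ref, materials$normal,
                       lambda_z)$lambda - (1 + target_pulsation),
      error = function(e) 10)  # past the limit point: stretch exceeds target
    scale <- stats::uniroot(f, c(1e-6, 1e3), tol = 1e-10)$root
    waveform <- waveform * scale
  }
  phases <- names(waveform)
  frames <- vector("list", length(phases))
  hoop <- lam <- vector("list", length(phases))
  s <- vessel$lumen$centerline$arclength
  for (k in seq_along(phases)) {
    eq <- solve_membrane_equilibrium(vessel, list(pressure = waveform[[k]]),
                                     materials, lambda_z, threshold)
    frames[[k]] <- vessel_frame(cbind(0, 0, lambda_z * s), eq$deformed_radius,
                                phase = phases[k], time_index = k - 1L)
    hoop[[k]] <- eq$hoop_stress
    lam[[k]] <- eq$lambda_theta
  }
  structure(list(frames = frames, L = L, C = C,
                 ground_truth = list(hoop_stress = hoop, lambda_theta = lam,
                                     waveform = waveform),
                 vessel = vessel, seed = NA_integer_),
            class = "sws_cardiac_sequence")
}

# a ring well inside the normal segment: midway between the ostium and the
# proximal lesion shoulder
normal_reference_ring <- function(vessel, threshold = 20) {
  prof <- compute_stenosis_profile(vessel$lumen, threshold = threshold)
  sten <- which(prof$labels == "stenotic")
  if (!length(sten)) return(max(2L, round(length(prof$labels) / 2)))
  max(2L, floor(min(sten) / 2))
}
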