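# End-to-end in-silico experiments: the closed-loop method-equivalence
# comparison against the force-based membrane solver, and the cohort
# peak-stress localization experiment.

#' Ring-wise circumferential and axial stretches of a matched configuration
#'
#' Per centerline ring, the circumferential stretch is the ratio of the
#' matched configuration's mean ring radius to the diastasis ring radius (the
#' ring-integrated element length ratio) and the axial stretch is the local
#' ratio of ring-centroid spacing along the centerline.
#'
#' @param propagation an `sws_propagation`.
#' @param k frame index within the propagation.
#' @return list with length-L vectors `lambda_theta` and `lambda_z`.
#' @export
ring_stretches <- function(propagation, k) {
  stopifnot(inherits(propagation, "sws_propagation"))
  ring_radii <- function(g) {
    ctr <- apply(g, c(1L, 3L), mean)
    rowMeans(sqrt((g[, , 1L] - ctr[, 1L])^2 + (g[, , 2L] - ctr[, 2L])^2 +
                    (g[, , 3L] - ctr[, 3L])^2))
  }
  seg_len <- function(g) {
    ctr <- apply(g, c(1L, 3L), mean)
    sqrt(rowSums((ctr[-1L, , drop = FALSE] - ctr[-nrow(ctr), , drop = FALSE])^2))
  }
  g0 <- propagation$grids[[1L]]
  gk <- propagation$grids[[k]]
  lt <- ring_radii(gk) / ring_radii(g0)
  sr <- seg_len(gk) / seg_len(g0)
  L <- length(lt)
  lz <- c(sr[1L], 0.5 * (sr[-1L] + sr[-(L - 1L)]), sr[L - 1L])
  list(lambda_theta = lt, lambda_z = lz)
}

#' Closed-loop comparison of inverse and force-based stress
#'
#' For every plaque composition x burden configuration, an idealized stenosis
#' model is forward-pressurized to a target normal-segment pulsation by the
#' axisymmetric membrane solver (the force-based comparator), the resulting
#' motion sequence is fed to the inverse pipeline (displacement mapping,
#' cumulative strain, lesion-aware Mooney-Rivlin stress), and the inverse
#' maximum principal Cauchy stress at a normal mid-segment ring at peak
#' pressure is compared with the forward hoop-stress ground truth. The
#' cycle-maximum lesion von Mises stress is also reported for ordering
#' analyses across compositions and burdens.
#'
#' @param compositions plaque compositions to cross.
#' @param burdens plaque burden fractions to cross.
#' @param remodeling remodeling class shared by all models.
#' @param target_pulsation normal-segment peak fractional diameter change.
#' @param L,C mesh dimensions.
#' @param search see [map_displacements()].
#' @param materials material table.
#' @return data.frame with one row per configuration: `composition`,
#'   `burden`, `forward_stress` (kPa), `inverse_stress` (kPa), `rel_error`,
#'   `throat_von_mises` (kPa), `throat_hoop_stress` (kPa, the
#'   circumferential superficial stress on the plaque at the throat),
#'   `lesion_max_von_mises` (kPa), `peak_pressure_kPa`.
#' @export
run_method_equivalence <- function(compositions = c("calcified", "fibrous", "lipid_rich"),
                                   burdens = c(0.509, 0.626, 0.691),
                                   remodeling = "none",
                                   target_pulsation = 0.12,
                                   L = 101L, C = 32L, search = list(),
                                   materials = default_materials()) {
  grid <- expand.grid(composition = compositions, burden = burdens,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    comp <- grid$composition[i]
    vessel <- make_stenosis_model(plaque_spec(comp, grid$burden[i], remodeling))
    seq_f <- forward_pressurized_sequence(vessel, materials = materials,
                                          target_pulsation = target_pulsation,
                                          L = L, C = C)
    prop <- propagate_cycle(seq_f, search)
    prof <- compute_stenosis_profile(prop$diastasis_mesh)
    strain <- compute_strain_series(prop, "cumulative")
    stress <- compute_stress_series(strain, prof,
                                    materials[c("normal", comp)],
                                    lesion_class = comp)
    k_peak <- which.max(seq_f$ground_truth$waveform)
    # normal mid-segment element: halfway between ostium and proximal shoulder
    i_ref <- max(1L, floor(min(which(prof$labels == "stenotic")) / 2))
    inv_sigma <- mean(stress[[k_peak]]$sigma1[i_ref, ])
    s_vessel <- vessel$lumen$centerline$arclength
    fwd_sigma <- stats::approx(s_vessel, seq_f$ground_truth$hoop_stress[[k_peak]],
                               xout = stress[[k_peak]]$element_arclength[i_ref])$y
    smry <- summarize_fields(strain, stress, prof)
    # stress on the plaque proper: element rows bounding the minimum-diameter
    # (throat) ring, where the material assignment is unambiguous
    rows_throat <- unique(pmin(pmax(c(prof$throat - 1L, prof$throat), 1L),
                               nrow(stress[[k_peak]]$von_mises)))
    # circumferential (hoop-direction) superficial Cauchy stress of the
    # plaque at the throat, from ring-circumference stretch ratios of the
    # matched configurations: the ring-integrated form of the element
    # length-ratio strain, insensitive to sub-ring matching slip because the
    # radius profile is stationary at the throat
    lt <- ring_stretches(prop, k_peak)
    hoop_inv <- mooney_rivlin_cauchy(
      list(lambda1 = lt$lambda_theta[prof$throat],
           lambda2 = lt$lambda_z[prof$throat],
           lambda3 = 1 / (lt$lambda_theta[prof$throat] *
                            lt$lambda_z[prof$throat])),
      materials[[comp]])$sigma1
    data.frame(composition = comp, burden = grid$burden[i],
               forward_stress = fwd_sigma, inverse_stress = inv_sigma,
               rel_error = abs(inv_sigma - fwd_sigma) / abs(fwd_sigma),
               throat_von_mises = mean(stress[[k_peak]]$von_mises[rows_throat, ]),
               throat_hoop_stress = mean(hoop_inv),
               lesion_max_von_mises = smry$lesion_max_von_mises,
               peak_pressure_kPa = max(seq_f$ground_truth$waveform),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort peak-stress localization experiment
#'
#' Runs the full inverse pipeline on a seeded cohort of synthetic sequences
#' with proximally-biased bending and classifies where the cycle-maximum von
#' Mises stress falls: proximal shoulder, throat, distal shoulder or normal
#' segment.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param L,C mesh dimensions.
#' @param search see [map_displacements()].
#' @param materials material table.
#' @return list with `locations` (per-sequence class), `table`
#'   (class counts), `fraction_lesion` (fraction of sequences whose peak lies
#'   in the shoulders or throat), and the per-sequence `summaries`.
#' @export
run_peak_location_experiment <- function(n = 16L, seed = 1L, L = 101L, C = 32L,
                                         search = list(),
                                         materials = default_materials()) {
  cohort <- make_validation_cohort(n, seed, L = L, C = C, proximal_bias = TRUE)
  summaries <- lapply(cohort, function(sq) {
    prop <- propagate_cycle(sq, search)
    prof <- compute_stenosis_profile(prop$diastasis_mesh)
    strain <- compute_strain_series(prop, "cumulative")
    comp <- sq$vessel$spec$composition
    stress <- compute_stress_series(strain, prof, materials[c("normal", comp)],
                                    lesion_class = comp)
    summarize_fields(strain, stress, prof)
  })
  locations <- vapply(summaries, `[[`, "", "peak_location")
  list(locations = locations,
       table = table(factor(locations, levels = c("proximal_shoulder", "throat",
                                                  "distal_shoulder", "normal"))),
       fraction_lesion = mean(locations != "normal"),
       summaries = summaries)
}
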