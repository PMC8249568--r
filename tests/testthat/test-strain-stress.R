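ref_quad <- function() rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), c(1, 0, 1))

test_that("element deformation gradients solve the edge least-squares problem", {
  q <- ref_quad()
  expect_equal(element_deformation_gradient(q, q), diag(2), tolerance = 1e-12)

  # 1.1x circumferential stretch (x is the circumferential direction here)
  q2 <- q; q2[, 1L] <- 1.1 * q2[, 1L]
  expect_equal(element_deformation_gradient(q, q2), diag(c(1.1, 1)),
               tolerance = 1e-12)

  # randomly perturbed quad: compare against an independent normal-equations
  # solve of min sum ||F a_k - b_k||^2 built with lsfit
  set.seed(3)
  for (i in 1:5) {
    qd <- q + matrix(rnorm(12, sd = 0.05), 4L, 3L)
    qd[, 2L] <- 0   # keep planar so both projections share the plane
    F <- element_deformation_gradient(q, qd)
    edges <- function(qq) rbind(qq[2, ] - qq[1, ], qq[4, ] - qq[3, ],
                                qq[3, ] - qq[1, ], qq[4, ] - qq[2, ])
    A <- edges(q)[, c(1L, 3L)]          # in-plane coordinates (x, z)
    # deformed basis as the implementation defines it
    u <- (qd[2, ] - qd[1, ]) + (qd[4, ] - qd[3, ]); u <- u / sqrt(sum(u^2))
    w <- (qd[3, ] - qd[1, ]) + (qd[4, ] - qd[2, ])
    vv <- w - sum(w * u) * u; vv <- vv / sqrt(sum(vv^2))
    B <- edges(qd) %*% cbind(u, vv)
    fit <- lsfit(A, B, intercept = FALSE)
    expect_equal(F, t(coef(fit)), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("principal stretches agree with the SVD and enforce incompressibility", {
  expect_equal(unname(principal_stretches(diag(2))), c(1, 1, 1))
  expect_equal(unname(principal_stretches(diag(c(1.1, 1)))),
               c(1.1, 1, 1 / 1.1), tolerance = 1e-12)
  Fs <- matrix(c(1, 0, 0.2, 1), 2L, 2L)   # simple shear, column-major
  ps <- principal_stretches(Fs)
  sv <- svd(Fs)$d
  expect_equal(unname(ps[1:2]), sv, tolerance = 1e-12)
  expect_equal(unname(ps[1L]), 1.10499, tolerance = 1e-5)
  expect_equal(unname(ps[2L]), 0.90499, tolerance = 1e-5)
  expect_equal(unname(prod(ps)), 1, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:20) {
    F <- diag(2) + matrix(rnorm(4, sd = 0.15), 2L, 2L)
    if (det(F) <= 0) next
    ps <- principal_stretches(F)
    expect_lt(abs(prod(ps) - 1), 1e-12)
  }
  expect_error(principal_stretches(diag(c(-1, 1))), "det")
})

# reduced plane-stress energy with incompressibility eliminated
W_reduced <- function(l1, l2, mat) {
  mat$c1 * (l1^2 + l2^2 + 1 / (l1 * l2)^2 - 3) +
    mat$c2 * (1 / l1^2 + 1 / l2^2 + (l1 * l2)^2 - 3)
}

test_that("Mooney-Rivlin Cauchy stresses match differentiation of the energy", {
  mats <- default_materials()
  expect_equal(mooney_rivlin_cauchy(c(1, 1, 1), mats$normal),
               list(sigma1 = 0, sigma2 = 0))

  # numeric differentiation oracle: sigma_k = lambda_k dW/dlambda_k over a
  # grid of biaxial states (constitutive consistency <= 1e-6 relative)
  h <- 1e-6
  for (mat in mats[c("normal", "calcified")]) {
    for (l1 in seq(0.8, 1.4, by = 0.15)) {
      for (l2 in seq(0.8, 1.4, by = 0.15)) {
        sg <- mooney_rivlin_cauchy(list(lambda1 = l1, lambda2 = l2,
                                        lambda3 = 1 / (l1 * l2)), mat)
        d1 <- l1 * (W_reduced(l1 + h, l2, mat) - W_reduced(l1 - h, l2, mat)) / (2 * h)
        d2 <- l2 * (W_reduced(l1, l2 + h, mat) - W_reduced(l1, l2 - h, mat)) / (2 * h)
        expect_equal(sg$sigma1, d1, tolerance = 1e-6)
        expect_equal(sg$sigma2, d2, tolerance = 1e-6)
      }
    }
  }

  # equibiaxial symmetry
  sg <- mooney_rivlin_cauchy(list(lambda1 = 1.1, lambda2 = 1.1,
                                  lambda3 = 1 / 1.21), mats$normal)
  expect_equal(sg$sigma1, sg$sigma2)

  # in-plane uniaxial: find lambda2 with sigma2 = 0, compare sigma1 with the
  # classical closed form 2 (l^2 - 1/l) (C1 + C2/l)
  mat <- mats$normal
  l1 <- 1.2
  f <- function(l2) mooney_rivlin_cauchy(list(lambda1 = l1, lambda2 = l2,
                                              lambda3 = 1 / (l1 * l2)), mat)$sigma2
  l2 <- uniroot(f, c(0.5, 1), tol = 1e-14)$root
  s1 <- mooney_rivlin_cauchy(list(lambda1 = l1, lambda2 = l2,
                                  lambda3 = 1 / (l1 * l2)), mat)$sigma1
  expect_equal(s1, 2 * (l1^2 - 1 / l1) * (mat$c1 + mat$c2 / l1),
               tolerance = 1e-9)
  expect_equal(l2, 1 / sqrt(l1), tolerance = 1e-6)  # uniaxial kinematics
})

test_that("von Mises reduction behaves at the plane-stress anchors", {
  expect_equal(von_mises(0, 0), 0)
  expect_equal(von_mises(100, 0), 100)
  expect_equal(von_mises(60, 60), 60)
})

test_that("strain series compose stretch ratios correctly", {
  fr <- straight_frame(n = 9L, length = 8)
  m <- build_structured_mesh(fr, L = 9L, C = 8L)
  g0 <- m$nodes

  # null motion
  prop <- fake_propagation(list(g0, g0, g0), m$arclength)
  for (mode in c("cumulative", "incremental")) {
    st <- compute_strain_series(prop, mode)
    expect_lt(max(abs(st[[3L]]$max_principal_strain)), 1e-12)
  }

  # single-step 12% inflation: circumferential strain 0.12 everywhere
  prop <- fake_propagation(list(g0, inflate_grid(g0, 1.12)), m$arclength)
  st <- compute_strain_series(prop, "cumulative")
  expect_equal(as.numeric(st[[2L]]$max_principal_strain),
               rep(0.12, 8L * 8L), tolerance = 1e-9)

  # two half-steps of 6%: cumulative strain is 1.06^2 - 1, not 0.12
  prop <- fake_propagation(list(g0, inflate_grid(g0, 1.06),
                                inflate_grid(g0, 1.06^2)), m$arclength)
  st_c <- compute_strain_series(prop, "cumulative")
  st_i <- compute_strain_series(prop, "incremental")
  expect_equal(mean(st_c[[3L]]$max_principal_strain), 1.06^2 - 1,
               tolerance = 1e-9)
  expect_equal(mean(st_i[[3L]]$max_principal_strain), 0.06, tolerance = 1e-9)

  # frame indifference: a rigid motion applied to every configuration leaves
  # the strain invariant
  R <- rot3(c(1, 2, 3), 0.7); tr <- c(5, -2, 1)
  move <- function(g) {
    flat <- sweep(matrix(g, ncol = 3L) %*% t(R), 2L, tr, `+`)
    array(flat, dim = dim(g))
  }
  prop_r <- fake_propagation(list(move(g0), move(inflate_grid(g0, 1.12))),
                             m$arclength)
  st_r <- compute_strain_series(prop_r, "cumulative")
  expect_equal(st_r[[2L]]$lambda1, st[[2L]]$lambda1, tolerance = 1e-9)

  expect_error(compute_strain_series(prop, "bogus"))
})

test_that("stress series apply lesion-aware materials and reduce correctly", {
  fr <- straight_frame(n = 9L, length = 8)
  m <- build_structured_mesh(fr, L = 9L, C = 8L)
  prof <- compute_stenosis_profile(m)
  mats <- default_materials()
  g0 <- m$nodes
  prop <- fake_propagation(list(g0, inflate_grid(g0, 1.10)), m$arclength)
  st <- compute_strain_series(prop, "cumulative")

  # zero strain gives zero stress regardless of materials
  ss0 <- compute_stress_series(compute_strain_series(
    fake_propagation(list(g0, g0), m$arclength), "cumulative"),
    prof, mats, lesion_class = "calcified")
  expect_equal(max(abs(ss0[[2L]]$von_mises)), 0, tolerance = 1e-10)

  # homogeneous uniform inflation: spatially constant von Mises
  ss <- compute_stress_series(st, prof, mats, lesion_class = "fibrous")
  expect_lt(diff(range(ss[[2L]]$von_mises)), 1e-9)

  # a stiffer lesion material scales stress by the constants' ratio exactly
  vfr <- make_stenosis_model(plaque_spec("fibrous", 0.626))$lumen
  mm <- build_structured_mesh(vfr, L = 41L, C = 8L)
  pprof <- compute_stenosis_profile(mm)
  pp <- fake_propagation(list(mm$nodes, inflate_grid(mm$nodes, 1.10)),
                         mm$arclength)
  pst <- compute_strain_series(pp, "cumulative")
  pss <- compute_stress_series(pst, pprof, mats, lesion_class = "fibrous")
  sten_rows <- which((pprof$labels[-41L] == "stenotic") &
                       (pprof$labels[-1L] == "stenotic"))
  nrm_rows <- which((pprof$labels[-41L] == "normal") &
                      (pprof$labels[-1L] == "normal"))
  ratio <- mean(pss[[2L]]$von_mises[sten_rows, ]) /
    mean(pss[[2L]]$von_mises[nrm_rows, ])
  expect_equal(ratio, 2, tolerance = 0.02)  # fibrous constants are 2x normal

  expect_error(compute_stress_series(st, prof, mats["calcified"]),
               "normal")
  expect_error(compute_stress_series(st, prof, mats["normal"],
                                     lesion_class = "fibrous"), "fibrous")
})

test_that("pulse stress localizes the systolic-diastolic difference", {
  fr <- straight_frame(n = 9L, length = 8)
  m <- build_structured_mesh(fr, L = 9L, C = 8L)
  prof <- compute_stenosis_profile(m)
  g0 <- m$nodes
  prop <- fake_propagation(list(g0, inflate_grid(g0, 1.05),
                                inflate_grid(g0, 1.12)), m$arclength)
  ss <- compute_stress_series(compute_strain_series(prop, "cumulative"),
                              prof, default_materials(), "fibrous")
  p0 <- pulse_stress(ss[[2L]], ss[[2L]])
  expect_equal(max(p0$pulse), 0)
  p <- pulse_stress(ss[[3L]], ss[[2L]])
  expect_true(all(p$pulse > 0))
  expect_equal(p$max, max(abs(ss[[3L]]$von_mises - ss[[2L]]$von_mises)))
  expect_true(is.finite(p$arclength_mm))

  small <- build_structured_mesh(fr, L = 5L, C = 8L)
  ss_small <- compute_stress_series(compute_strain_series(
    fake_propagation(list(small$nodes, small$nodes), small$arclength),
    "cumulative"), compute_stenosis_profile(small), default_materials(), "fibrous")
  expect_error(pulse_stress(ss[[2L]], ss_small[[2L]]), "topology")
})

test_that("cycle summaries average segments and classify the peak location", {
  fr <- straight_frame(n = 21L, length = 20)
  m <- build_structured_mesh(fr, L = 21L, C = 8L)
  prof <- compute_stenosis_profile(m)
  g0 <- m$nodes
  prop <- fake_propagation(list(g0, inflate_grid(g0, 1.12)), m$arclength)
  st <- compute_strain_series(prop, "cumulative")
  ss <- compute_stress_series(st, prof, default_materials(), "fibrous")
  sm <- summarize_fields(st, ss, prof)
  expect_equal(sm$peak_location, "normal")
  expect_true(is.na(sm$strain_stenotic))
  expect_equal(sm$strain_normal, 0.12 / 2, tolerance = 1e-9)  # avg with diastasis
})
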