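# Procrustes superimposition of corresponded 3D curves and the cohort-level
# centerline-prediction experiment.

#' Procrustes superimposition of two corresponded point sets
#'
#' Both sets are centered and standardized to unit centroid size
#' (`||X - mean||_F = 1`); the rotation maximizing their alignment is found by
#' SVD with reflections disallowed (anatomical curves preserve chirality).
#' The scaling factor is the optimal full-Procrustes scale applied to the raw
#' centered `Y` to superimpose it on `X` (1 for congruent shapes; a pure size
#' change appears here and nowhere else), and the dissimilarity is the
#' residual sum of squares after centering, unit-size standardization,
#' rotation and optimal scaling, bounded in `[0, 1]`.
#'
#' @param X,Y n x 3 matrices of corresponded points (n >= 3). `Y` is
#'   superimposed onto `X`.
#' @return object of class `sws_procrustes`: list with `scaling`,
#'   `dissimilarity`, `rotation` (3 x 3, det +1), `translation` (the
#'   difference of centroids), `Yhat` (the aligned standardized `Y`).
#' @export
procrustes <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3L || nrow(X) < 3L)
    stop("X and Y must be matching n x 3 point sets with n >= 3", call. = FALSE)
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2L, cx); Y0 <- sweep(Y, 2L, cy)
  nx <- sqrt(sum(X0^2)); ny <- sqrt(sum(Y0^2))
  if (nx == 0 || ny == 0)
    stop("degenerate point set: zero centroid size", call. = FALSE)
  Xs <- X0 / nx; Ys <- Y0 / ny
  M <- crossprod(Xs, Ys)        # 3x3; rotation R maximizes tr(R %*% M)
  sv <- svd(M)
  if (qr(M)$rank < 2L)
    warning("rank-deficient configuration (collinear points); solution may not be unique",
            call. = FALSE)
  d <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))   # forbid reflections
  R <- sv$v %*% d %*% t(sv$u)   # applied as Ys %*% R
  trace <- sum(sv$d * diag(d))
  scaling <- trace * nx / ny     # optimal scale applied to the raw centered Y
  dissimilarity <- max(0, 1 - trace^2)
  structure(list(scaling = scaling, dissimilarity = dissimilarity,
                 rotation = R, translation = cx - cy,
                 Yhat = trace * Ys %*% R),
            class = "sws_procrustes")
}

#' Cohort centerline-prediction experiment
#'
#' For every sequence of the cohort one non-diastasis frame is drawn (from a
#' single RNG stream seeded by `seed`), its centerline is predicted by
#' propagating the energy-minimizing displacement mapping around the
#' remaining cycle with piecewise-linear time interpolation, and the
#' prediction is compared against the frame's true centerline by
#' index-corresponded Procrustes superimposition.
#'
#' @param cohort list of `sws_cardiac_sequence`s (each >= 4 frames).
#' @param seed integer seed for the held-out frame draws.
#' @param search see [map_displacements()].
#' @return object of class `sws_prediction_experiment`: list with `results`
#'   (per-sequence data.frame: sequence, held_out_frame, scaling,
#'   dissimilarity, error or NA), `mean_scaling`, `sd_scaling`,
#'   `mean_dissimilarity`, `sd_dissimilarity`, `n`, `n_failed`.
#' @export
run_prediction_experiment <- function(cohort, seed = 1L, search = list()) {
  stopifnot(length(cohort) >= 1L)
  ks <- with_seed(seed, vapply(cohort, function(sq) {
    K <- length(sq$frames)
    if (K < 4L) stop("each sequence needs at least 4 frames", call. = FALSE)
    sample(2:K, 1L)
  }, 1L))
  rows <- lapply(seq_along(cohort), function(i) {
    sq <- cohort[[i]]
    k <- ks[[i]]
    out <- tryCatch({
      pred <- predict_frame(sq, k, search)
      true_mesh <- build_structured_mesh(sq$frames[[k]], L = sq$L, C = sq$C)
      truth <- mesh_centerline(true_mesh)
      pr <- procrustes(truth, pred$centerline$points)
      data.frame(sequence = i, held_out_frame = k, scaling = pr$scaling,
                 dissimilarity = pr$dissimilarity, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(sequence = i, held_out_frame = k, scaling = NA_real_,
                 dissimilarity = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE))
    out
  })
  results <- do.call(rbind, rows)
  ok <- is.na(results$error)
  structure(list(results = results,
                 mean_scaling = mean(results$scaling[ok]),
                 sd_scaling = stats::sd(results$scaling[ok]),
                 mean_dissimilarity = mean(results$dissimilarity[ok]),
                 sd_dissimilarity = stats::sd(results$dissimilarity[ok]),
                 n = nrow(results), n_failed = sum(!ok)),
            class = "sws_prediction_experiment")
}
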