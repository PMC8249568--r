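# File formats and reporting. Vessel-frame sequences travel as plain CSV
# (one row per centerline point: frame_index, phase, x_mm, y_mm, z_mm,
# radius_mm); meshes export to OBJ or legacy-VTK quad polydata; reports are
# schema-versioned JSON. Column names carry units; mmHg is converted to kPa
# once at the boundary, never internally.

SEQUENCE_COLUMNS <- c("frame_index", "phase", "x_mm", "y_mm", "z_mm", "radius_mm")

#' Write a cardiac sequence to a CSV file
#'
#' @param sequence an `sws_cardiac_sequence` or list of `sws_vessel_frame`s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(sequence, path) {
  frames <- if (inherits(sequence, "sws_cardiac_sequence")) sequence$frames
  else sequence
  tabs <- lapply(frames, function(f) {
    data.frame(frame_index = f$time_index, phase = f$phase,
               x_mm = f$centerline$points[, 1L],
               y_mm = f$centerline$points[, 2L],
               z_mm = f$centerline$points[, 3L],
               radius_mm = f$radius, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cardiac sequence from CSV
#'
#' Accepts a single CSV holding multiple `frame_index` values or a directory
#' of per-frame CSVs. Frames are sorted by `frame_index`; the sequence must
#' contain at least two frames with consistent point counts, all coordinates
#' and radii finite, and exactly one diastasis frame (reported first if its
#' `frame_index` is the smallest, as written by the generator).
#'
#' @param path CSV file or directory of CSV files.
#' @param L,C mesh dimensions to record with the sequence (defaults 101, 32).
#' @return an `sws_cardiac_sequence` (without ground truth).
#' @export
read_sequence <- function(path, L = 101L, C = 32L) {
  files <- if (dir.exists(path))
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  else path
  if (!length(files)) stop(sprintf("no CSV files found at '%s'", path), call. = FALSE)
  tab <- do.call(rbind, lapply(files, function(f) {
    x <- utils::read.csv(f, stringsAsFactors = FALSE, blank.lines.skip = TRUE)
    missing <- setdiff(SEQUENCE_COLUMNS, names(x))
    if (length(missing))
      stop(sprintf("%s: missing columns: %s", f, paste(missing, collapse = ", ")),
           call. = FALSE)
    num <- c("x_mm", "y_mm", "z_mm", "radius_mm")
    bad <- !stats::complete.cases(x[num]) | !apply(is.finite(as.matrix(x[num])), 1L, all)
    if (any(bad))
      stop(sprintf("%s: non-finite coordinate or radius at data line %d",
                   f, which(bad)[1L]), call. = FALSE)
    x[SEQUENCE_COLUMNS]
  }))
  idx <- sort(unique(tab$frame_index))
  if (length(idx) < 2L)
    stop("a sequence needs at least 2 frames", call. = FALSE)
  counts <- table(tab$frame_index)
  if (length(unique(as.integer(counts))) != 1L)
    stop(sprintf("inconsistent point counts across frames: %s",
                 paste(sprintf("frame %s: %d", names(counts), counts),
                       collapse = "; ")), call. = FALSE)
  frames <- lapply(idx, function(i) {
    fr <- tab[tab$frame_index == i, ]
    phase <- unique(fr$phase)
    if (length(phase) != 1L)
      stop(sprintf("frame %s carries multiple phase labels", i), call. = FALSE)
    vessel_frame(cbind(fr$x_mm, fr$y_mm, fr$z_mm), fr$radius_mm,
                 phase = phase, time_index = i)
  })
  n_dia <- sum(vapply(frames, `[[`, "", "phase") == "diastasis")
  if (n_dia != 1L)
    stop(sprintf("a sequence must contain exactly one diastasis frame (found %d)",
                 n_dia), call. = FALSE)
  structure(list(frames = frames, L = as.integer(L), C = as.integer(C),
                 ground_truth = NULL, seed = NA_integer_),
            class = "sws_cardiac_sequence")
}

#' Export a structured mesh to OBJ or legacy VTK polydata
#'
#' @param mesh an `sws_mesh`.
#' @param path output path.
#' @param format `"obj"` (quad faces) or `"vtk"` (legacy ASCII polydata).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("obj", "vtk")) {
  format <- match.arg(format)
  stopifnot(inherits(mesh, "sws_mesh"))
  L <- mesh$L; C <- mesh$C
  verts <- matrix(mesh$nodes, ncol = 3L)   # node (i,j) at row (j-1)*L + i
  id <- function(i, j) (j - 1L) * L + i
  i <- rep(seq_len(L - 1L), C)
  j <- rep(seq_len(C), each = L - 1L)
  jp <- j %% C + 1L
  quads <- cbind(id(i, j), id(i, jp), id(i + 1L, jp), id(i + 1L, j))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "obj") {
    writeLines("# structured vessel surface mesh (units: mm)", con)
    writeLines(sprintf("v %.9g %.9g %.9g", verts[, 1L], verts[, 2L], verts[, 3L]), con)
    writeLines(sprintf("f %d %d %d %d", quads[, 1L], quads[, 2L], quads[, 3L],
                       quads[, 4L]), con)
  } else {
    writeLines(c("# vtk DataFile Version 3.0",
                 "structured vessel surface mesh (units: mm)",
                 "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d double", nrow(verts))), con)
    writeLines(sprintf("%.9g %.9g %.9g", verts[, 1L], verts[, 2L], verts[, 3L]), con)
    writeLines(sprintf("POLYGONS %d %d", nrow(quads), 5L * nrow(quads)), con)
    writeLines(sprintf("4 %d %d %d %d", quads[, 1L] - 1L, quads[, 2L] - 1L,
                       quads[, 3L] - 1L, quads[, 4L] - 1L), con)
  }
  invisible(path)
}

#' Assemble a machine-readable analysis report
#'
#' Collects cycle summaries, pulse-stress localization and Procrustes
#' validation into one schema-versioned structure; written as JSON when
#' `path` is given. Positions are arclength from the proximal (ostial) end in
#' mm; stresses kPa.
#'
#' @param summary output of [summarize_fields()] (or `NULL`).
#' @param pulse output of [pulse_stress()] (or `NULL`).
#' @param procrustes_summary output of [run_prediction_experiment()] (or
#'   `NULL`).
#' @param path optional JSON output path.
#' @return the report list, invisibly when writing.
#' @export
report <- function(summary = NULL, pulse = NULL, procrustes_summary = NULL,
                   path = NULL) {
  rep <- list(
    schema_version = "1.0",
    units = list(length = "mm", stress = "kPa", strain = "dimensionless"),
    segment_summary = if (is.null(summary)) NULL else list(
      time_avg_max_principal_strain = list(normal = summary$strain_normal,
                                           stenotic = summary$strain_stenotic),
      time_avg_von_mises_kPa = list(normal = summary$stress_normal,
                                    stenotic = summary$stress_stenotic),
      peak_location = summary$peak_location,
      peak_stress_kPa = summary$peak_stress,
      peak_arclength_mm = summary$peak_arclength_mm),
    pulse_stress = if (is.null(pulse)) NULL else list(
      max_kPa = pulse$max, arclength_mm = pulse$arclength_mm),
    procrustes = if (is.null(procrustes_summary)) NULL else list(
      mean_scaling = procrustes_summary$mean_scaling,
      sd_scaling = procrustes_summary$sd_scaling,
      mean_dissimilarity = procrustes_summary$mean_dissimilarity,
      sd_dissimilarity = procrustes_summary$sd_dissimilarity,
      n = procrustes_summary$n, n_failed = procrustes_summary$n_failed),
    complete = !is.null(summary))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(rep))
  }
  rep
}

#' Load and validate a run configuration
#'
#' YAML configuration with explicit range validation; unknown keys are
#' rejected. Recognized keys: `mesh` (`L`, `C`), `mapping` (`alpha_deform`,
#' `alpha_kinetic`, `axial_halfwidth`, `maxit`, `reltol`), `materials`
#' (tissue class -> `c1`, `c2` in kPa), `stenosis_threshold` (percent),
#' `seed`, `pressure_unit` (`"kPa"` or `"mmHg"`; mmHg values are converted
#' once on load).
#'
#' @param path YAML file path.
#' @return validated configuration list with a `materials` entry of
#'   `sws_material` objects.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configurations", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("mesh", "mapping", "materials", "stenosis_threshold", "seed",
             "pressure_unit")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop(sprintf("unknown configuration keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  out <- list(mesh = list(L = 101L, C = 32L),
              mapping = default_search(),
              materials = default_materials(),
              stenosis_threshold = 20, seed = 1L, pressure_unit = "kPa")
  if (!is.null(cfg$mesh)) {
    if (!is.null(cfg$mesh$L)) {
      if (cfg$mesh$L < 4) stop("mesh$L must be >= 4", call. = FALSE)
      out$mesh$L <- as.integer(cfg$mesh$L)
    }
    if (!is.null(cfg$mesh$C)) {
      if (cfg$mesh$C < 8) stop("mesh$C must be >= 8", call. = FALSE)
      out$mesh$C <- as.integer(cfg$mesh$C)
    }
  }
  if (!is.null(cfg$mapping)) {
    m <- cfg$mapping
    if (!is.null(m$alpha_deform) || !is.null(m$alpha_kinetic)) {
      w <- c(m$alpha_deform %||% 1, m$alpha_kinetic %||% 0.1)
      if (any(w < 0)) stop("mapping weights must be >= 0", call. = FALSE)
      out$mapping$weights <- w
    }
    for (k in c("axial_halfwidth", "maxit", "reltol"))
      if (!is.null(m[[k]])) {
        if (m[[k]] <= 0) stop(sprintf("mapping$%s must be > 0", k), call. = FALSE)
        out$mapping[[k]] <- m[[k]]
      }
  }
  if (!is.null(cfg$stenosis_threshold)) {
    if (cfg$stenosis_threshold <= 0 || cfg$stenosis_threshold >= 100)
      stop("stenosis_threshold must lie in (0, 100)", call. = FALSE)
    out$stenosis_threshold <- cfg$stenosis_threshold
  }
  if (!is.null(cfg$seed)) out$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$pressure_unit)) {
    out$pressure_unit <- match.arg(cfg$pressure_unit, c("kPa", "mmHg"))
  }
  if (!is.null(cfg$materials)) {
    for (cls in names(cfg$materials)) {
      mc <- cfg$materials[[cls]]
      out$materials[[cls]] <- material_model(mc$c1, mc$c2, cls)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
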