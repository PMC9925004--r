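# Configuration, reproducible experiment drivers, reference-table ingestion
# and file I/O (legacy-VTK meshes/fields, CSV traces, YAML configs).

#' Load the reference study tables
#'
#' Typed records transcribed from the reference ex-vivo biventricular study
#' cohort that the synthetic anatomies emulate: model descriptions
#' (myocardial volumes of the detailed/smoothed pairs), per-heart anatomy
#' summaries, electrophysiological markers, pseudo-ECG RMSD values,
#' programmed-stimulation event counts, and detailed-minus-smoothed marker
#' differences. These enable the aggregate comparisons with no simulation.
#'
#' @param dir directory containing the fixture CSVs (default: the copies
#'   installed with the package).
#' @return named list of data.frames: `models`, `hearts`, `markers`,
#'   `ecg_rmsd`, `vt_events`, `geometry_diffs`.
#' @export
load_reference_tables <- function(dir = system.file("extdata",
                                                    package = "cardiosim")) {
  schemas <- list(
    models = c("heart", "sex", "geometry", "myocardial_volume_cm3"),
    hearts = c("heart", "sex", "trabecular_volume_pct",
               "n_false_tendons_geq_1cm"),
    markers = c("heart", "geometry", "sex", "QRS", "QRS_diff", "CV", "QT",
                "QT_diff", "TAT", "TAT10", "TAT90", "EDI"),
    ecg_rmsd = c("heart", "sex", "LI", "LII", "LIII"),
    vt_events = c("geometry", "sex", "site", "events", "simulations"),
    geometry_diffs = c("heart", "sex", "QRS_Gdiff", "CV_Gdiff", "QT_Gdiff",
                       "TAT_Gdiff", "TAT10_Gdiff", "TAT90_Gdiff",
                       "EDI_Gdiff"))
  out <- lapply(names(schemas), function(nm) {
    f <- file.path(dir, paste0("reference_", nm, ".csv"))
    if (!file.exists(f)) stop("missing reference table: ", f)
    tab <- read.csv(f, stringsAsFactors = FALSE)
    missing <- setdiff(schemas[[nm]], names(tab))
    if (length(missing))
      stop("reference table '", nm, "' lacks column(s): ",
           paste(missing, collapse = ", "))
    tab
  })
  names(out) <- names(schemas)
  out
}

#' Run the sinus-rhythm experiment matrix
#'
#' Executes sinus simulations for every combination of heart geometry
#' (detailed/smoothed) and sex phenotype, extracts the activation and ECG
#' markers, and computes the difference markers, the detailed-vs-smoothed
#' pseudo-ECG RMSD per sex, and the Welch comparison of QT by sex.
#'
#' @param hearts named list; each entry is either a single `cardiac_mesh`
#'   or a list with elements `detailed` and `smoothed`.
#' @param sexes phenotypes to run.
#' @param n_beats,cycle_length_ms pacing protocol of each run.
#' @param stimuli_fn function(mesh) returning the stimulus list; defaults
#'   to [place_iars()] on biventricular meshes and an end-stimulus strip
#'   otherwise.
#' @param init_beats,dt_ms,snapshot_dt_ms forwarded to [run_simulation()].
#' @param out_dir optional directory; when given, records, traces and the
#'   echoed configuration are written there.
#' @param seed echoed into the configuration (simulation stages are
#'   deterministic given a mesh).
#' @return list with `records` (one row per matrix cell), `ecgs` (named
#'   list of `ecg_trace`), `diffs` ([difference_markers()] output), `rmsd`
#'   (detailed-vs-smoothed per heart and sex) and `welch_qt`.
#' @export
run_matrix <- function(hearts, sexes = c("male", "female"), n_beats = 1,
                       cycle_length_ms = 600, stimuli_fn = NULL,
                       init_beats = 150, dt_ms = 0.01, snapshot_dt_ms = 1,
                       baseline_tol_frac = 0.05, out_dir = NULL, seed = 1) {
  records <- NULL
  ecgs <- list()
  for (hname in names(hearts)) {
    entry <- hearts[[hname]]
    geoms <- if (inherits(entry, "cardiac_mesh")) list(detailed = entry)
      else entry
    for (gname in names(geoms)) {
      mesh <- geoms[[gname]]
      fibers <- if (!is.null(mesh$meta$kind) &&
                    mesh$meta$kind == "biventricular")
        assign_fibers(mesh) else uniform_fibers(mesh)
      stims <- if (!is.null(stimuli_fn)) stimuli_fn(mesh)
        else if (!is.null(mesh$meta$kind) && mesh$meta$kind == "biventricular")
          place_iars(mesh)
        else stimulus_site("edge", which(mesh$nodes[, 1] <=
                                           min(mesh$nodes[, 1]) + 0.1),
                           0, -80, 2)
      for (sex in sexes) {
        cellname <- paste(hname, gname, sex, sep = "_")
        res <- tryCatch(
          run_simulation(mesh, fibers, stimuli = stims, sex = sex,
                         n_beats = n_beats,
                         cycle_length_ms = cycle_length_ms,
                         dt_ms = dt_ms, snapshot_dt_ms = snapshot_dt_ms,
                         init_beats = init_beats),
          error = function(e) {
            message("run_matrix: cell ", cellname, " failed: ",
                    conditionMessage(e))
            NULL
          })
        if (is.null(res)) next
        am <- activation_markers(res)
        ecg <- compute_pseudo_ecg(res, fibers)
        ecgs[[cellname]] <- ecg
        onset <- res$analysis_start - min(res$snapshot_times)
        cv <- tryCatch(apparent_cv(res), error = function(e) NA_real_)
        records <- rbind(records, data.frame(
          heart = hname, geometry = gname,
          sex = if (sex == "male") "M" else "F",
          QRS = qrs_duration(ecg, res$analysis_start,
                             baseline_tol_frac = baseline_tol_frac),
          QT = qt_interval(ecg, res$analysis_start,
                           baseline_tol_frac = baseline_tol_frac),
          TAT = am$TAT, TAT10 = am$TAT10, TAT90 = am$TAT90, EDI = am$EDI,
          CV = cv, activated = activated_fraction(res)))
      }
    }
  }
  diffs <- if (!is.null(records) && length(unique(records$sex)) > 1)
    difference_markers(records) else NULL
  # detailed-vs-smoothed ECG RMSD per heart and sex
  rmsd <- NULL
  for (hname in names(hearts)) for (sex in c("male", "female")) {
    a <- ecgs[[paste(hname, "detailed", sex, sep = "_")]]
    b <- ecgs[[paste(hname, "smoothed", sex, sep = "_")]]
    if (is.null(a) || is.null(b)) next
    r <- ecg_rmsd(a, b)
    rmsd <- rbind(rmsd, data.frame(heart = hname,
                                   sex = if (sex == "male") "M" else "F",
                                   LI = r["LI"], LII = r["LII"],
                                   LIII = r["LIII"], row.names = NULL))
  }
  welch_qt <- NULL
  if (!is.null(records)) {
    qm <- records$QT[records$sex == "M"]
    qf <- records$QT[records$sex == "F"]
    if (length(qm) >= 2 && length(qf) >= 2 && !anyNA(c(qm, qf)))
      welch_qt <- welch_ttest(qf, qm)
  }
  out <- list(records = records, ecgs = ecgs, diffs = diffs, rmsd = rmsd,
              welch_qt = welch_qt,
              config = list(sexes = sexes, n_beats = n_beats,
                            cycle_length_ms = cycle_length_ms,
                            dt_ms = dt_ms, seed = seed,
                            version = as.character(
                              utils::packageVersion("cardiosim"))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(records, file.path(out_dir, "biomarker_records.csv"),
              row.names = FALSE)
    for (nm in names(ecgs))
      write_ecg(ecgs[[nm]], file.path(out_dir, paste0("ecg_", nm, ".csv")))
    yaml::write_yaml(out$config, file.path(out_dir, "run_config.yaml"))
  }
  out
}

# ---------------- legacy VTK I/O ----------------

#' Write a mesh (and fields) as legacy ASCII VTK
#'
#' Unstructured tetrahedral grid with the region label as cell data and the
#' transmural/apicobasal coordinates (plus any extra fields) as point data.
#'
#' @param mesh a `cardiac_mesh`.
#' @param file output path.
#' @param point_data named list of per-node scalars or 3-column matrices.
#' @param cell_data named list of per-element scalars.
#' @export
write_vtk <- function(mesh, file, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "cardiosim mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  write(t(mesh$nodes), con, ncolumns = 3)
  writeLines(paste("CELLS", m, m * 5), con)
  write(t(cbind(4L, mesh$elems - 1L)), con, ncolumns = 5)
  writeLines(paste("CELL_TYPES", m), con)
  write(rep(10L, m), con, ncolumns = 10)
  if (!is.null(mesh$phi)) point_data$phi <- mesh$phi
  if (!is.null(mesh$z_ab)) point_data$z <- mesh$z_ab
  cell_data$region <- as.integer(mesh$region)
  if (length(point_data)) {
    writeLines(paste("POINT_DATA", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(paste("VECTORS", nm, "double"), con)
        write(t(v), con, ncolumns = 3)
      } else {
        writeLines(c(paste("SCALARS", nm, "double 1"),
                     "LOOKUP_TABLE default"), con)
        write(v, con, ncolumns = 9)
      }
    }
  }
  if (length(cell_data)) {
    writeLines(paste("CELL_DATA", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(paste("SCALARS", nm, "double 1"),
                   "LOOKUP_TABLE default"), con)
      write(cell_data[[nm]], con, ncolumns = 9)
    }
  }
  invisible(file)
}

#' Read a legacy ASCII VTK unstructured tetrahedral mesh
#'
#' Minimal reader for the files produced by [write_vtk()] (and compatible
#' exports): POINTS, CELLS of type 10, and scalar POINT_DATA/CELL_DATA.
#'
#' @param file path.
#' @return a `cardiac_mesh` (region restored from the `region` cell field
#'   when present; other fields returned in `meta$fields`).
#' @export
read_vtk <- function(file) {
  txt <- readLines(file)
  toks <- strsplit(trimws(txt), "\\s+")
  find <- function(word) which(vapply(toks, function(x)
    length(x) > 0 && x[1] == word, TRUE))
  ip <- find("POINTS")[1]
  n <- as.integer(toks[[ip]][2])
  nums <- suppressWarnings(as.numeric(unlist(toks[(ip + 1):length(toks)])))
  nodes <- matrix(nums[1:(3 * n)], ncol = 3, byrow = TRUE)
  ic <- find("CELLS")[1]
  m <- as.integer(toks[[ic]][2])
  cvals <- suppressWarnings(as.integer(unlist(toks[(ic + 1):length(toks)])))[1:(5 * m)]
  cells <- matrix(cvals, ncol = 5, byrow = TRUE)
  if (any(cells[, 1] != 4L)) stop("only tetrahedral cells are supported")
  elems <- cells[, 2:5] + 1L
  fields <- list()
  region <- rep("myocardium", m)
  isc <- find("SCALARS")
  for (k in isc) {
    nm <- toks[[k]][2]
    count <- if (any(find("POINT_DATA") < k) &&
                 (!length(find("CELL_DATA")) || k < find("CELL_DATA")[1]))
      n else m
    vals <- suppressWarnings(as.numeric(unlist(toks[(k + 2):length(toks)])))[1:count]
    if (nm == "region")
      region <- c("myocardium", "fast_endo", "trabecula", "false_tendon",
                  "border_zone", "dense_scar")[as.integer(vals)]
    else fields[[nm]] <- vals
  }
  # voxel pitch estimate from the first element's shortest edge
  dx <- min(dist(nodes[elems[1, ], ]))
  mesh <- .new_mesh(nodes, elems, region, dx,
                    meta = list(kind = "imported", fields = fields))
  if (!is.null(fields$phi)) mesh$phi <- fields$phi
  if (!is.null(fields$z)) mesh$z_ab <- fields$z
  if (!is.null(mesh$phi)) mesh <- .assign_layers(mesh)
  mesh
}

#' Save / load a run configuration
#'
#' Configurations are fully serializable; a run re-executed from its echoed
#' configuration is bit-identical for the deterministic stages.
#'
#' @param config named list (must include a `seed`).
#' @param file YAML path.
#' @export
save_run_config <- function(config, file) {
  if (is.null(config$seed)) stop("run configuration must carry a seed")
  yaml::write_yaml(config, file)
  invisible(file)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(file) yaml::read_yaml(file)
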