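# File formats and the pipeline driver: OpenSim storage (.sto/.mot)
# dialect, CSV fallback, YAML run configuration, run manifests.
# All angles are degrees in files and radians internally.

#' Read a time-series table (.sto/.mot or CSV)
#'
#' Parses the OpenSim storage dialect: free header lines, `nRows=`,
#' `nColumns=`, `endheader`, a tab-delimited column-label line, then the
#' numeric body.  Files ending in `.csv` are read as comma-separated with a
#' header row.  The first column must be time, strictly increasing.
#'
#' @param path File path.
#' @return A `time_series_table`: list with `time`, `data` (matrix, named
#'   columns), `labels`, `units`, `name`.
#' @export
read_storage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, check.names = FALSE)
    return(new_tst(as.matrix(df), basename(path)))
  }
  lines <- readLines(path)
  hdr_end <- which(trimws(lines) == "endheader")
  if (length(hdr_end) == 0)
    stop("not a storage file: missing 'endheader' (", path, ")")
  hdr_end <- hdr_end[1]
  hdr <- lines[seq_len(hdr_end - 1)]
  get_num <- function(key) {
    ln <- grep(paste0("^", key, "="), hdr, value = TRUE)
    if (length(ln) == 0) return(NA_integer_)
    as.integer(sub(paste0("^", key, "="), "", ln[1]))
  }
  n_rows <- get_num("nRows"); n_cols <- get_num("nColumns")
  in_degrees <- any(grepl("^inDegrees=yes", hdr))
  labels <- strsplit(trimws(lines[hdr_end + 1]), "[\t ]+")[[1]]
  body <- lines[(hdr_end + 2):length(lines)]
  body <- body[nzchar(trimws(body))]
  rows <- strsplit(trimws(body), "[\t ]+")
  nfield <- lengths(rows)
  if (length(unique(nfield)) != 1)
    stop(sprintf("ragged storage body in %s: line %d has %d fields, expected %d",
                 path, which(nfield != nfield[1])[1] + hdr_end + 1,
                 nfield[which(nfield != nfield[1])[1]], nfield[1]))
  M <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  if (!is.na(n_rows) && n_rows != nrow(M))
    stop(sprintf("nRows mismatch in %s: header says %d, found %d",
                 path, n_rows, nrow(M)))
  if (!is.na(n_cols) && n_cols != ncol(M))
    stop(sprintf("nColumns mismatch in %s: header says %d, found %d",
                 path, n_cols, ncol(M)))
  colnames(M) <- labels
  tst <- new_tst(M, sub("\\.[^.]*$", "", basename(path)))
  tst$in_degrees <- in_degrees
  tst
}

new_tst <- function(M, name) {
  if (ncol(M) < 2) stop("time-series table needs a time column and data")
  tcol <- M[, 1]
  if (any(diff(tcol) <= 0)) stop("time column must be strictly increasing")
  structure(list(time = tcol, data = M[, -1, drop = FALSE],
                 labels = colnames(M)[-1], name = name,
                 units = rep("", ncol(M) - 1)),
            class = "time_series_table")
}

#' Write a time-series table (.sto or CSV by extension)
#'
#' @param table A `time_series_table` (or list with `time` and `data`).
#' @param path Output path; `.csv` selects CSV, anything else the storage
#'   dialect.
#' @param in_degrees Value of the `inDegrees` header flag.
#' @export
write_storage <- function(table, path, in_degrees = TRUE) {
  M <- cbind(time = table$time, table$data)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(as.data.frame(M), path, row.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(table$name %||% "predgait",
               "version=1",
               sprintf("nRows=%d", nrow(M)),
               sprintf("nColumns=%d", ncol(M)),
               sprintf("inDegrees=%s", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(colnames(M), collapse = "\t")), con)
  utils::write.table(format(M, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML)
#'
#' Validates the section structure: known top-level keys only
#' (`model`, `condition`, `ocp`, `analysis`, `synthetic`, `seed`,
#' `output_dir`).
#'
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("model", "condition", "ocp", "analysis", "synthetic", "seed",
             "output_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg
}

#' Default pipeline run configuration
#'
#' A small demo configuration: amputee model, REF condition, synthetic
#' trials and whole-curve statistics.
#' @export
default_run_config <- function() {
  list(
    model = list(variant = "amputee", mass = 68.5, height = 1.78,
                 d_mpk = 1.0),
    condition = "REF",
    ocp = list(n_mesh = 50, target_speed = 1.48),
    analysis = list(alpha = 0.05, dtw_window = 0.05),
    synthetic = list(n_trials = 5),
    seed = 1L,
    output_dir = "predgait_run"
  )
}

config_model <- function(mcfg) {
  variant <- mcfg$variant %||% "healthy"
  if (variant == "healthy")
    build_reference_model(mcfg$mass %||% 77.8, mcfg$height %||% 1.81)
  else if (variant == "amputee")
    build_amputee_model(mcfg$mass %||% 68.5, mcfg$height %||% 1.78,
                        prosthesis_spec(d_mpk = mcfg$d_mpk %||% 1.0))
  else if (variant == "hypothetical_healthy") {
    am <- build_amputee_model(mcfg$amputee_mass %||% 68.5,
                              mcfg$height %||% 1.78)
    mirror_to_hypothetical_healthy(am, mcfg$mass %||% 72.1)
  } else stop("unknown model variant: ", variant)
}

#' Run the pipeline stages
#'
#' Executes the requested stages in dependency order and writes every
#' artifact plus a manifest (config hash, seed, solver statistics, package
#' version) into the output directory.  Reruns with an identical
#' configuration and seed reproduce identical numeric outputs.
#'
#' @param config A configuration list (see [read_run_config()]) or a path
#'   to a YAML file.
#' @param stages Subset of `c("synth", "estimate", "predict", "analyze")`.
#' @return The output directory, invisibly; the manifest is
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("synth", "analyze")) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- match.arg(stages, c("synth", "estimate", "predict", "analyze"),
                      several.ok = TRUE)
  out <- config$output_dir %||% "predgait_run"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  manifest <- list(
    config_hash = fnv1a_hash(jsonlite::toJSON(config, auto_unbox = TRUE)),
    seed = seed,
    package_version = as.character(utils::packageVersion("predgait")),
    stages = stages, artifacts = list(), solver = list())
  model <- config_model(config$model %||% list())

  if ("analyze" %in% stages && !"synth" %in% stages &&
      !file.exists(file.path(out, "synth_knee_angle.csv")))
    stop("stage 'analyze' needs synthetic trials: run stage 'synth' first")

  if ("synth" %in% stages) {
    scfg <- config$synthetic %||% list()
    gen <- generate_trials(synthetic_gait_config(
      n_trials = scfg$n_trials %||% 5, seed = seed,
      knee_limit_deg = scfg$knee_limit_deg))
    for (nm in names(gen$curves)) {
      f <- file.path(out, paste0("synth_", nm, ".csv"))
      utils::write.csv(t(gen$curves[[nm]]$trials), f, row.names = FALSE)
      manifest$artifacts[[paste0("synth_", nm)]] <- basename(f)
    }
  }
  if ("estimate" %in% stages) {
    ds <- generate_estimation_dataset(model, seed = seed)
    est <- estimate_parameters(model, estimation_problem_spec(
      ds, n_mesh = config$ocp$n_mesh_estimation %||% 25))
    f <- file.path(out, "estimated_parameters.csv")
    utils::write.csv(est$parameters, f, row.names = FALSE)
    manifest$artifacts$estimated_parameters <- basename(f)
    manifest$solver$estimation <- est$solver
  }
  if ("predict" %in% stages) {
    ps <- prediction_problem_spec(
      target_speed = config$ocp$target_speed %||% 1.48,
      condition = config$condition %||% "REF",
      n_mesh = config$ocp$n_mesh %||% 50)
    pred <- predict_gait(model, ps)
    tab <- list(time = pred$trajectories$time,
                data = cbind(rad2deg(pred$trajectories$q)))
    write_storage(tab, file.path(out, "prediction_kinematics.sto"))
    manifest$artifacts$prediction_kinematics <- "prediction_kinematics.sto"
    manifest$solver$prediction <- pred$solver[c("status", "iterations",
                                                "feasibility")]
    manifest$prediction <- list(T = pred$T, dist = pred$dist,
                                speed = pred$dist / pred$T,
                                objective = pred$objective)
  }
  if ("analyze" %in% stages) {
    acfg <- config$analysis %||% list()
    ref <- generate_trials(synthetic_gait_config(
      n_trials = config$synthetic$n_trials %||% 5, seed = seed))
    skg <- generate_trials(synthetic_gait_config(
      n_trials = config$synthetic$n_trials %||% 5, seed = seed + 1000L,
      knee_limit_deg = acfg$knee_limit_deg %||% 20))
    spm <- spm_paired_nonparametric(ref$curves$knee_angle,
                                    skg$curves$knee_angle,
                                    alpha = acfg$alpha %||% 0.05)
    spm_df <- data.frame(pct = 0:100, t = spm$t_curve,
                         supra = abs(spm$t_curve) > spm$t_crit)
    f <- file.path(out, "spm_knee_angle.csv")
    utils::write.csv(spm_df, f, row.names = FALSE)
    manifest$artifacts$spm_knee_angle <- basename(f)
    dtw <- dtw_matrix(
      list(knee = colMeans(ref$curves$knee_angle$trials)),
      list(knee = colMeans(skg$curves$knee_angle$trials)),
      window_frac = acfg$dtw_window %||% 0.05)
    f <- file.path(out, "dtw_scores.csv")
    utils::write.csv(dtw, f, row.names = FALSE)
    manifest$artifacts$dtw_scores <- basename(f)
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}
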