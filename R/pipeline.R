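.config_schema <- list(
  mode = "simulate | files",
  out_dir = "output directory",
  seed = "integer seed",
  sequence = c("n_echoes", "echo_spacing", "t1_assumed"),
  grid = c("t2_min", "t2_max", "n_points"),
  fit = c("chi2_low", "chi2_high", "flip_min", "flip_max", "flip_step",
          "cutoff"),
  roi = c("min_voxels"),
  stats = c("family_alpha", "conf", "rois", "tests"),
  inputs = c("volume", "wm", "rois", "lesions", "cohort_csv")
)

#' Pipeline configuration
#'
#' Builds and validates the configuration consumed by [run_pipeline()].
#' Unknown keys (top-level or within a section) are rejected with a message
#' listing them, so typos fail loudly rather than silently using defaults.
#'
#' @param ... named settings overriding the defaults; sections are
#'   `mode`, `out_dir`, `seed`, `sequence`, `grid`, `fit`, `roi`, `stats`,
#'   `inputs` (see the fields in the validated default below).
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    mode = "simulate",
    out_dir = file.path(tempdir(), "mwimhi_run"),
    seed = 1L,
    sequence = list(n_echoes = 48L, echo_spacing = 0.008, t1_assumed = 1.0),
    grid = list(t2_min = 0.015, t2_max = 2.0, n_points = 40L),
    fit = list(chi2_low = 1.02, chi2_high = 1.025, flip_min = 90,
               flip_max = 180, flip_step = 5, cutoff = 0.040),
    roi = list(min_voxels = 50L),
    stats = list(family_alpha = 0.05, conf = 0.95,
                 rois = c("slf", "cc", "cingulum"),
                 tests = c("sdmt", "srt", "cowat", "bvmtr")),
    inputs = list(volume = NULL, wm = NULL, rois = NULL, lesions = NULL,
                  cohort_csv = NULL)
  )
  user <- list(...)
  validate_config_keys(user, defaults, "config")
  cfg <- utils::modifyList(defaults, user)
  if (!cfg$mode %in% c("simulate", "files"))
    stop("mode must be 'simulate' or 'files'", call. = FALSE)
  if (cfg$fit$chi2_low < 1 || cfg$fit$chi2_high <= cfg$fit$chi2_low)
    stop("fit$chi2_low/high must satisfy 1 <= low < high", call. = FALSE)
  if (cfg$stats$family_alpha <= 0 || cfg$stats$family_alpha >= 1)
    stop("stats$family_alpha must lie in (0, 1)", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

validate_config_keys <- function(user, defaults, where) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown %s key(s): %s (known: %s)", where,
                 paste(unknown, collapse = ", "),
                 paste(names(defaults), collapse = ", ")), call. = FALSE)
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(user[[nm]]))
      validate_config_keys(user[[nm]], defaults[[nm]], paste0(where, "$", nm))
  }
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config file.
#' @return validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(paste(deparse(unclass(cfg)), collapse = "\n"), tf)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis end to end: obtain a multi-echo volume and
#' masks (simulated via [make_toy_fixture()] in `"simulate"` mode, or read
#' from the configured NIfTI paths), fit the voxelwise MWF map, compute
#' per-ROI NAWM statistics (erosion, WM intersection, lesion subtraction,
#' MHI), obtain a cohort table (simulated or read from CSV), and run the
#' correlation matrix and group comparisons. Writes the MWF/flip/residual
#' maps (NIfTI), `roi_stats.csv`, `correlations.csv`,
#' `group_comparisons.json` and `run_log.txt` under `config$out_dir`.
#'
#' A missing lesion mask is treated as an empty mask with a logged warning
#' (controls have no lesions). The run is deterministic: configuration plus
#' seed fully determine every CSV output.
#'
#' @param config a [pipeline_config()].
#' @return report list: `mwf_map`, `roi_stats`, `correlations`,
#'   `group_comparisons`, `outputs` (file paths), `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_lines <- c(sprintf("mwimhi %s", as.character(utils::packageVersion("mwimhi"))),
                 sprintf("config_hash %s", hash),
                 sprintf("seed %d", config$seed),
                 sprintf("mode %s", config$mode))

  seqp <- grase_sequence(n_echoes = config$sequence$n_echoes,
                         echo_spacing = config$sequence$echo_spacing,
                         t1_assumed = config$sequence$t1_assumed)
  grid <- t2_grid(config$grid$t2_min, config$grid$t2_max, config$grid$n_points)
  flips <- seq(config$fit$flip_min, config$fit$flip_max, by = config$fit$flip_step)

  if (config$mode == "simulate") {
    fx <- make_toy_fixture(seed = config$seed)
    vol <- fx$phantom$volume4d
    wm <- fx$phantom$masks$wm
    roi_masks <- fx$phantom$masks[setdiff(names(fx$phantom$masks),
                                          c("wm", "lesions"))]
    lesions <- fx$phantom$masks$lesions
    cohort <- fx$cohort
    log_lines <- c(log_lines, "stage simulate: toy fixture generated")
  } else {
    vol <- read_nifti_vol(config$inputs$volume, expect_dims = 4)
    wm <- read_mask(config$inputs$wm)
    check_alignment(vol, wm, config$inputs$volume, config$inputs$wm)
    roi_masks <- lapply(config$inputs$rois, read_mask)
    for (nm in names(roi_masks))
      check_alignment(vol, roi_masks[[nm]], config$inputs$volume,
                      config$inputs$rois[[nm]])
    if (is.null(config$inputs$lesions) || !file.exists(config$inputs$lesions)) {
      warning("no lesion mask provided; treating lesions as empty", call. = FALSE)
      log_lines <- c(log_lines, "stage inputs: lesion mask missing, using empty mask")
      lesions <- array(0L, dim(vol)[1:3])
    } else {
      lesions <- read_mask(config$inputs$lesions)
      check_alignment(vol, lesions, config$inputs$volume, config$inputs$lesions)
    }
    cohort <- if (!is.null(config$inputs$cohort_csv))
      read.csv(config$inputs$cohort_csv, comment.char = "#",
               stringsAsFactors = FALSE) else NULL
  }

  fit <- tryCatch(
    fit_volume(vol, fit_mask = wm, grid = grid, seq = seqp,
               chi2_window = c(config$fit$chi2_low, config$fit$chi2_high),
               flip_candidates = flips, cutoff = config$fit$cutoff),
    error = function(e) stop("stage fit failed: ", conditionMessage(e),
                             call. = FALSE))
  log_lines <- c(log_lines,
                 sprintf("stage fit: %d fitted, %d skipped, %d window violations",
                         fit$n_fitted, fit$n_skipped, fit$n_window_violations))

  out_paths <- list(
    mwf = file.path(config$out_dir, "mwf.nii.gz"),
    flip = file.path(config$out_dir, "flip.nii.gz"),
    residual = file.path(config$out_dir, "residual.nii.gz"),
    roi_stats = file.path(config$out_dir, "roi_stats.csv"),
    correlations = file.path(config$out_dir, "correlations.csv"),
    group_comparisons = file.path(config$out_dir, "group_comparisons.json"),
    log = file.path(config$out_dir, "run_log.txt")
  )
  affine <- attr(vol, "affine")
  write_nifti_vol(fit$mwf, out_paths$mwf, affine)
  write_nifti_vol(fit$flip, out_paths$flip, affine)
  write_nifti_vol(fit$residual, out_paths$residual, affine)

  stats_tab <- tryCatch(
    roi_stats(fit, wm, roi_masks, lesions = lesions,
              min_voxels = config$roi$min_voxels, subject_id = "subject01"),
    error = function(e) stop("stage roi-stats failed for subject01: ",
                             conditionMessage(e), call. = FALSE))
  write_commented_csv(stats_tab, out_paths$roi_stats, hash,
                      units = "mean_mwf=fraction sd_mwf=fraction mhi=dimensionless")
  log_lines <- c(log_lines, sprintf("stage roi-stats: %d ROIs", nrow(stats_tab)))

  corr <- NULL; gc_rep <- NULL
  if (!is.null(cohort)) {
    corr <- run_correlation_matrix(cohort, rois = config$stats$rois,
                                   tests = config$stats$tests,
                                   family_alpha = config$stats$family_alpha,
                                   conf = config$stats$conf)
    write_commented_csv(corr, out_paths$correlations, hash,
                        units = "r=dimensionless p=probability")
    gc_rep <- group_comparisons(cohort)
    jsonlite::write_json(
      list(groups = gc_rep$groups, continuous = gc_rep$continuous,
           sex = list(statistic = gc_rep$sex$statistic, df = gc_rep$sex$df,
                      p = gc_rep$sex$p)),
      out_paths$group_comparisons, auto_unbox = TRUE, digits = NA)
    log_lines <- c(log_lines,
                   sprintf("stage correlate: %d correlation rows", nrow(corr)))
  }

  writeLines(log_lines, out_paths$log)
  list(mwf_map = fit, roi_stats = stats_tab, correlations = corr,
       group_comparisons = gc_rep, outputs = out_paths, config_hash = hash)
}
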