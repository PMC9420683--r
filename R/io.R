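#' Read a time-enhancement curve from CSV
#'
#' Curve files are plain UTF-8 CSV with the exact header `time_s,hu`: one
#' row per frame, time in seconds and ROI median HU. Parse problems are
#' reported with the offending line number.
#'
#' @param path Path to a curve CSV file.
#' @return A [te_curve()].
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty curve file: ", path)
  header <- trimws(strsplit(lines[1L], ",", fixed = TRUE)[[1L]])
  if (length(header) < 2L || header[1L] != "time_s" || header[2L] != "hu")
    stop(path, ": line 1: expected header 'time_s,hu', got '", lines[1L], "'")
  if (length(lines) < 2L) stop(path, ": no data rows")

  n <- length(lines) - 1L
  times <- numeric(n); values <- numeric(n)
  for (i in seq_len(n)) {
    cells <- trimws(strsplit(lines[i + 1L], ",", fixed = TRUE)[[1L]])
    if (length(cells) < 2L)
      stop(path, ": line ", i + 1L, ": expected 2 comma-separated cells")
    tv <- suppressWarnings(as.numeric(cells[1:2]))
    if (any(is.na(tv)))
      stop(path, ": line ", i + 1L, ": non-numeric cell in '", lines[i + 1L], "'")
    times[i] <- tv[1L]; values[i] <- tv[2L]
  }
  if (n >= 2L && any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L]
    stop(path, ": line ", bad + 2L, ": times must be strictly increasing")
  }
  te_curve(times, values)
}

#' Write a time-enhancement curve to CSV
#'
#' Inverse of [read_curve()]; values are printed with enough digits that a
#' write/read round trip reproduces them exactly.
#'
#' @param curve A [te_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "te_curve"))
  lines <- c("time_s,hu",
             sprintf("%.17g,%.17g", curve$times, curve$values))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a synthetic study to a directory
#'
#' Writes `aorta.csv` plus one `<organ>.csv` per organ (format of
#' [write_curve()]) and a `truth.json` manifest with the generating
#' configuration and per-organ ground truth (true perfusion, peak
#' enhancement, curve parameters).
#'
#' @param study A `ct_study` from [generate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ct_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_curve(study$aortic_curve, file.path(dir, "aorta.csv"))
  for (org in names(study$organ_curves))
    write_curve(study$organ_curves[[org]], file.path(dir, paste0(org, ".csv")))
  truth <- list(
    config = unclass(study$config),
    aorta = list(y_max = study$aorta_truth$params$y_max,
                 t_max = study$aorta_truth$params$t_max,
                 alpha = study$aorta_truth$params$alpha,
                 baseline_hu = study$aorta_truth$baseline_hu),
    organs = lapply(study$truth, function(tr)
      list(perfusion_per_s = tr$perfusion,
           perfusion_per_min = tr$perfusion_per_min,
           y_max = tr$y_max,
           t_max = tr$params$t_max,
           alpha = tr$params$alpha,
           baseline_hu = tr$baseline_hu)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study configuration from JSON or YAML
#'
#' Accepts a file holding the fields of [study_config()] (any subset;
#' missing fields keep their defaults). Files ending in `.yaml`/`.yml` are
#' parsed as YAML (requires the yaml package), anything else as JSON.
#'
#' @param path Path to a JSON or YAML configuration file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(raw)) stop(path, ": config must be a mapping of fields")
  # organs may arrive as a data-frame-ish structure from JSON; normalise
  if (!is.null(raw$organs) && is.data.frame(raw$organs))
    raw$organs <- lapply(split(raw$organs, rownames(raw$organs)), as.list)
  allowed <- names(formals(study_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop(path, ": unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(study_config, raw)
}

#' Export a study as a voxelised 4D phantom volume
#'
#' Renders a synthetic study as a small NIfTI volume (one cuboid region
#' per curve, background air at -1000 HU) so the simulated kinetics can be
#' inspected in standard imaging tools. Voxel values in each region follow
#' the corresponding noiseless-plus-noise ROI curve exactly.
#'
#' @param study A `ct_study` from [generate_study()].
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param region_dim Edge length in voxels of each region's cube.
#' @return `path`, invisibly.
#' @export
export_phantom <- function(study, path, region_dim = 4L) {
  stopifnot(inherits(study, "ct_study"))
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("exporting phantoms requires the 'RNifti' package")
  curves <- c(list(aorta = study$aortic_curve), study$organ_curves)
  n_reg <- length(curves)
  nx <- region_dim * n_reg + n_reg + 1L
  ny <- region_dim + 2L
  nt <- study$config$n_frames
  vol <- array(-1000, dim = c(nx, ny, region_dim, nt))
  for (i in seq_along(curves)) {
    x0 <- (i - 1L) * (region_dim + 1L) + 2L
    for (f in seq_len(nt))
      vol[x0:(x0 + region_dim - 1L), 2L:(ny - 1L), , f] <- curves[[i]]$values[f]
  }
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(1, 1, 1, study$config$frame_interval)
  RNifti::writeNifti(img, path)
  invisible(path)
}
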