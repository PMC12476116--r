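#' Read a subject table from tab-delimited text
#'
#' Expects a header row; required columns are `subject_id`, `group`,
#' `crp`, `age`, `sex` and `education`. Numeric columns are checked
#' cell by cell and a malformed value is reported with its file line
#' number. Empty strings and `NA` are honored as missing.
#'
#' @param path path to a TSV file.
#' @return data frame of class `subject_table`.
#' @export
read_subject_table <- function(path) {
  .assert(file.exists(path), paste0("file not found: ", path), "path")
  raw <- read.delim(path, colClasses = "character", na.strings = c("NA", ""),
                    check.names = FALSE)
  req <- c("subject_id", "group", "crp", "age", "sex", "education")
  miss <- setdiff(req, names(raw))
  .assert(length(miss) == 0,
          paste0("missing required columns: ", paste(miss, collapse = ", ")))
  num_cols <- setdiff(names(raw), c("subject_id", "group"))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(!is.na(raw[[cn]]) & is.na(v))
    if (length(bad))
      stop(sprintf("malformed numeric value in column '%s' at line %d: '%s'",
                   cn, bad[1] + 1L, raw[[cn]][bad[1]]), call. = FALSE)
    raw[[cn]] <- v
  }
  .assert(all(is.na(raw$crp) | raw$crp >= 0), "CRP must be non-negative (mg/L)")
  class(raw) <- c("subject_table", "data.frame")
  raw
}

#' Write a subject table as tab-delimited text
#'
#' @param subjects data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(subjects, path) {
  write.table(subjects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a volume as NIfTI-1
#'
#' Stores the array in double precision so a round trip through
#' [read_volume()] preserves the voxel data bit-exactly.
#'
#' @param arr 3D or 4D numeric array.
#' @param path output path (`.nii` or `.nii.gz`; plain `.nii` keeps the
#'   file text-tool friendly in pipelines that hash outputs).
#' @param voxel_size isotropic voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(arr, path, voxel_size = 3) {
  img <- RNifti::asNifti(arr, pixdim = rep(voxel_size, min(3, length(dim(arr)))))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return numeric array with attribute `pixdim`.
#' @export
read_volume <- function(path) {
  .assert(file.exists(path), paste0("file not found: ", path), "path")
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "pixdim") <- RNifti::pixdim(img)
  out
}

#' Assemble and validate a pipeline configuration
#'
#' All tunable parameters of [run_pipeline()] with their defaults:
#' cohort and grid settings, the fALFF band, the cluster-forming p,
#' permutation/surrogate/bootstrap counts, the FDR level and the
#' per-stage seeds (all derived from `seed` unless given).
#'
#' @param seed master integer seed.
#' @param ... overrides for any default listed below.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_patients = 120, n_controls = 118,
    grid_shape = c(24, 24, 24), n_timepoints = 200, tr = 2, voxel_size = 3,
    n_regions = 60, n_genes = 500, n_categories = 25,
    k_neuro_maps = 27, k_behav_maps = 50,
    band = c(0.01, 0.1), spectrum = "amplitude",
    cluster_p = 0.001, n_perm = 1000, n_surr = 1000, n_boot = 5000,
    fdr_q = 0.05, alpha = 0.05,
    skeleton_voxels = 200, skeleton_planted = 61:90,
    covariates_falff = c("age", "sex", "education", "fd"),
    covariates_dti = c("age", "sex", "education"),
    sensitivity_bmi = FALSE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  .assert(length(unknown) == 0,
          paste0("unknown config fields: ", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  for (f in c("cluster_p", "fdr_q", "alpha"))
    .assert(cfg[[f]] > 0 && cfg[[f]] < 1, "must be in (0,1)", f)
  for (f in c("n_perm", "n_surr", "n_boot"))
    .assert(cfg[[f]] >= 1, "must be a positive integer", f)
  .assert(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be one integer",
          "seed")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path `.json` (or `.yaml`/`.yml`, if the yaml package is
#'   installed) file of overrides for [pipeline_config()].
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  .assert(file.exists(path), paste0("file not found: ", path), "path")
  vals <- if (grepl("\\.ya?ml$", path)) {
    .assert(requireNamespace("yaml", quietly = TRUE), "yaml package required for YAML config")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, vals)
}
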