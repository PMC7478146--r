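CONTAINER_VERSION <- 1L

.container_classes <- c("sensor_array", "epoched_recording", "source_grid",
                        "source_estimate", "stat_map", "leadfield_grid",
                        "spatial_filter", "sphere_head_model")

#' Save / load a domain object as a versioned container
#'
#' Containers are self-describing files holding one domain object (sensor
#' array, epoched recording, source grid, lead field, source estimate, stat
#' map, ...) together with a format-version attribute. Round-trips are
#' lossless: arrays are restored bit-identically and all metadata is
#' preserved. Loading re-validates the object's class invariants; a corrupt
#' payload or an unknown container version raises an explicit error rather
#' than silently truncating.
#'
#' @param obj one of the package's domain objects.
#' @param path file path to write to / read from.
#' @return `save_container` returns `path` invisibly; `load_container`
#'   returns the restored object.
#' @export
save_container <- function(obj, path) {
  cls <- class(obj)[1]
  if (!cls %in% .container_classes)
    stop_mg("cannot save object of class '%s'; supported: %s", cls,
            paste(.container_classes, collapse = ", "))
  payload <- list(container_version = CONTAINER_VERSION, class = cls,
                  object = unclass(obj))
  saveRDS(payload, path, version = 3L)
  invisible(path)
}

#' @rdname save_container
#' @export
load_container <- function(path) {
  if (!file.exists(path)) stop_mg("container file not found: %s", path)
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop_mg("unreadable container %s: %s",
                                                  path, conditionMessage(e)))
  if (!is.list(payload) || is.null(payload$container_version))
    stop_mg("%s is not a recognised container (no version field)", path)
  if (payload$container_version != CONTAINER_VERSION)
    stop_mg("unknown container version %s (this build reads version %d)",
            payload$container_version, CONTAINER_VERSION)
  obj <- payload$object
  cls <- payload$class
  # revalidate through the constructor where one exists; structural
  # corruption (e.g. a truncated array) must fail loudly here
  out <- switch(cls,
    sensor_array = sensor_array(obj$channel_id, obj$position, obj$orientation,
                                obj$coil_type, obj$baseline),
    epoched_recording = epoched_recording(obj$data, obj$sfreq, obj$times,
                                          obj$condition),
    source_grid = source_grid(obj$origin, obj$spacing, obj$shape,
                              obj$inside_mask),
    source_estimate = {
      g <- source_grid(obj$grid$origin, obj$grid$spacing, obj$grid$shape,
                       obj$grid$inside_mask)
      source_estimate(obj$values, obj$kind, g, obj$windows, obj$bands,
                      obj$method, obj$provenance)
    },
    stat_map = {
      g <- if (!is.null(obj$grid))
        source_grid(obj$grid$origin, obj$grid$spacing, obj$grid$shape,
                    obj$grid$inside_mask)
      stat_map(obj$pseudo_t, obj$p_uncorrected, obj$p_fwer, obj$p_fdr,
               obj$clusters, obj$n_subjects, obj$n_permutations, obj$test,
               g, obj$windows, obj$bands)
    },
    structure(obj, class = cls))
  out
}

#' Export one window/band slice of a source estimate as NIfTI-1
#'
#' Writes the selected slice onto the full lattice of the estimate's grid.
#' Outside-mask voxels are written as `NaN` so downstream thresholding tools
#' ignore them. The NIfTI sform affine maps 0-based lattice indices to the
#' grid's mm head-frame (RAS) coordinates.
#'
#' @param est a [source_estimate()].
#' @param window,band 1-based window and band indices.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
export_nifti <- function(est, window = 1L, band = 1L, path) {
  d <- dim(est$values)
  if (window < 1 || window > d[2] || band < 1 || band > d[3])
    stop_mg("window/band index out of range (have %d windows, %d bands)",
            d[2], d[3])
  g <- est$grid
  vol <- array(NaN, g$shape)
  vol[g$inside_idx] <- est$values[, window, band]
  img <- RNifti::asNifti(vol)
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(rep(g$spacing, 3))
  aff[1:3, 4] <- g$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Grid affine (lattice index -> mm)
#'
#' The 4x4 matrix mapping 0-based lattice indices of a [source_grid()] to mm
#' RAS coordinates; identical to the sform written by [export_nifti()].
#' @param grid a [source_grid()].
#' @export
grid_affine <- function(grid) {
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(rep(grid$spacing, 3))
  aff[1:3, 4] <- grid$origin
  aff
}

#' Read a group-analysis pointer file
#'
#' A pointer file is a manifest of per-subject result containers used by the
#' group statistics stage: TSV with header columns `path`, `subject_id`,
#' `group`, `condition` (a JSON array of objects with the same keys is also
#' accepted). All referenced files must exist and (subject, condition) pairs
#' must be unique.
#'
#' @param path pointer file (`.tsv`/`.txt` or `.json`).
#' @param base_dir directory against which relative paths are resolved;
#'   defaults to the pointer file's directory.
#' @return A `data.frame` of class `pointer_file`.
#' @export
read_pointer <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop_mg("pointer file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("path", "subject_id", "group", "condition")
  if (nrow(df) == 0) stop_mg("pointer file %s has no entries", path)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_mg("pointer file missing columns: %s", paste(missing_cols, collapse = ", "))
  df <- df[need]
  df$subject_id <- as.character(df$subject_id)
  key <- paste(df$subject_id, df$condition, sep = "\r")
  if (anyDuplicated(key))
    stop_mg("duplicate (subject, condition) entries: %s",
            paste(unique(paste0("(", df$subject_id[duplicated(key)], ", ",
                                df$condition[duplicated(key)], ")")),
                  collapse = ", "))
  abs_path <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                     file.path(base_dir, df$path))
  gone <- !file.exists(abs_path)
  if (any(gone))
    stop_mg("pointer references missing file(s): %s",
            paste(df$path[gone], collapse = ", "))
  df$path <- abs_path
  class(df) <- c("pointer_file", "data.frame")
  df
}
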