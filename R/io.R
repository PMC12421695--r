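#' Write / read BIDS-style events tables
#'
#' Events are tab-separated UTF-8 with a "." decimal point and `n/a` for
#' missing values, columns `onset`, `duration`, `trial_type` (`"heart"` /
#' `"target"`), `block_index`. `write_events()` accepts a `run_schedule` (its
#' [schedule_events()] table is written) or an events data frame;
#' `read_events()` validates the columns and the trial-type vocabulary and
#' returns the events data frame.
#'
#' @param x A `run_schedule` or events data frame.
#' @param path File path (`*_events.tsv`).
#' @return `read_events()` returns the events data frame; `write_events()`
#'   returns `path` invisibly.
#' @export
write_events <- function(x, path) {
  ev <- if (inherits(x, "run_schedule")) schedule_events(x) else x
  stopifnot(all(c("onset", "duration", "trial_type", "block_index") %in% names(ev)))
  out <- ev
  out[] <- lapply(out, function(col) {
    col <- as.character(col); col[is.na(col)] <- "n/a"; col
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = "n/a", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("onset", "duration", "trial_type", "block_index")
  missing_cols <- setdiff(need, names(ev))
  if (length(missing_cols))
    stop("events file missing column(s): ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(ev$trial_type), c("heart", "target"))
  if (length(bad))
    stop("unknown trial_type value(s): ", paste(bad, collapse = ", "))
  ev$onset <- as.numeric(ev$onset)
  ev$duration <- as.numeric(ev$duration)
  ev$block_index <- as.integer(ev$block_index)
  ev
}

#' Export / import an ROI run as NIfTI
#'
#' `export_nifti()` lays the ROI voxels on a synthetic 3-D grid (a cube just
#' large enough to hold them), writes a 4-D NIfTI file with the TR in the
#' header, and returns the voxel mask used. `import_nifti()` reads the file
#' back and recovers the volumes x voxels matrix given that mask (columns in
#' mask order). Requires the \pkg{RNifti} package.
#'
#' @param ts A `roi_timeseries` object.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param mask For `import_nifti()`: integer matrix of voxel grid coordinates
#'   (one row per voxel, columns x/y/z, 1-based) as returned by
#'   `export_nifti()`.
#' @param tr_seconds Expected TR; a header mismatch is an error.
#' @return `export_nifti()`: the mask, invisibly. `import_nifti()`: a
#'   volumes x voxels matrix.
#' @export
export_nifti <- function(ts, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI export")
  stopifnot(inherits(ts, "roi_timeseries"))
  n_vox <- ncol(ts$data); n_vol <- nrow(ts$data)
  side <- ceiling(n_vox^(1 / 3))
  grid <- as.matrix(expand.grid(x = 1:side, y = 1:side, z = 1:side))[1:n_vox, , drop = FALSE]
  arr <- array(0, dim = c(side, side, side, n_vol))
  for (v in seq_len(n_vox))
    arr[grid[v, 1], grid[v, 2], grid[v, 3], ] <- ts$data[, v]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(3, 3, 3, ts$params$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(grid)
}

#' @rdname export_nifti
#' @export
import_nifti <- function(path, mask, tr_seconds = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI import")
  img <- RNifti::readNifti(path)
  if (!is.null(tr_seconds)) {
    tr_file <- RNifti::pixdim(img)[4]
    if (abs(tr_file - tr_seconds) > 1e-6)
      stop("TR mismatch: header has ", tr_file, ", expected ", tr_seconds)
  }
  arr <- as.array(img)
  n_vol <- dim(arr)[4]
  out <- matrix(NA_real_, n_vol, nrow(mask))
  for (v in seq_len(nrow(mask)))
    out[, v] <- arr[mask[v, 1], mask[v, 2], mask[v, 3], ]
  out
}

#' Serialise decoder and sham models to JSON
#'
#' Documented flat JSON layouts: the decoder model stores `weights`, `bias`,
#' `c_param`, `platt_a`, `platt_b` and `trained_on_runs`; the sham model
#' stores bins, distributions, per-bin pools, transition table and run
#' success rates.
#'
#' @param model A `decoder_model` or `sham_model`.
#' @param path Output path.
#' @return The reader returns the reconstructed object.
#' @export
write_decoder_model <- function(model, path) {
  stopifnot(inherits(model, "decoder_model"))
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_decoder_model
#' @export
read_decoder_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = as.numeric(m$weights), bias = as.numeric(m$bias),
                 c_param = as.numeric(m$c_param),
                 platt_a = as.numeric(m$platt_a),
                 platt_b = as.numeric(m$platt_b),
                 trained_on_runs = as.integer(m$trained_on_runs)),
            class = "decoder_model")
}

#' @rdname write_decoder_model
#' @export
write_sham_model <- function(model, path) {
  stopifnot(inherits(model, "sham_model"))
  out <- unclass(model)
  out$cache <- NULL  # derived; rebuilt on read
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_decoder_model
#' @export
read_sham_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(bin_width = as.numeric(m$bin_width),
                          breaks = as.numeric(m$breaks),
                          unconditional = as.numeric(m$unconditional),
                          pools = lapply(m$pools, as.numeric),
                          transition = matrix(as.numeric(m$transition),
                                              nrow = nrow(m$transition)),
                          transition_n = as.numeric(m$transition_n),
                          run_success_rates = as.numeric(m$run_success_rates),
                          condition_on = m$condition_on),
                     class = "sham_model")
  model$cache <- build_sham_cache(model)
  model
}

#' Stream feedback records to TSV
#'
#' One row per trial with all [trial_feedback()] fields, in the same TSV
#' dialect as the events tables.
#'
#' @param records Feedback records data frame.
#' @param path Output path.
#' @export
write_feedback_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Small deterministic test fixture bundle
#'
#' A tiny cohort (2 NF + 2 sham subjects, 20 voxels, full run structure) and
#' a hand-checkable heartbeat table, regenerated byte-identically from the
#' seed. Used across the test suite; also a convenient quick-start object.
#'
#' @param seed Integer seed.
#' @return List with `config`, `cohort`, `heartbeat` (a 6-trial table whose
#'   reported counts equal its recorded counts) and `seed`.
#' @export
make_fixtures <- function(seed = 42L) {
  config <- cohort_config(n_nf = 2L, n_sham = 2L,
                          params = acquisition_params(n_voxels = 20L))
  cohort <- simulate_cohort(2L, 2L, config, seed = seed)
  heartbeat <- data.frame(
    duration_seconds = c(15, 25, 35, 45, 55, 65),
    recorded_beats = c(17, 29, 41, 52, 64, 75),
    reported_beats = c(17, 29, 41, 52, 64, 75),
    confidence = rep(70, 6)
  )
  list(config = config, cohort = cohort, heartbeat = heartbeat, seed = seed)
}
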