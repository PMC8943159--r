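#' Read a 4D BOLD NIfTI file
#'
#' @param path NIfTI-1 file path.
#' @param tr Fallback repetition time in seconds when the header carries
#'   none.
#' @return List: `data` (4D array), `tr` (seconds), `image` (the RNifti
#'   object, retaining the affine for map writing).
#' @export
load_bold <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4)
    stop("dimensionality error: expected a 4D BOLD image, got ",
         length(dim(img)), "D")
  pd <- RNifti::pixdim(img)
  hdr_tr <- if (length(pd) >= 4) pd[4] else NA_real_
  if (!is.finite(hdr_tr) || hdr_tr <= 0) {
    if (is.null(tr)) stop("metadata error: TR missing from header and not supplied")
    hdr_tr <- tr
  }
  list(data = img[], tr = hdr_tr, image = img)
}

#' Write a 3D/4D array as NIfTI-1
#'
#' @param data Numeric array.
#' @param path Output path (`.nii`).
#' @param voxel_size_mm Spatial voxel dimensions.
#' @param tr TR in seconds (4D only).
#' @return `path`, invisibly.
#' @export
write_bold <- function(data, path, voxel_size_mm = c(3.1, 3.1, 5), tr = 2) {
  pd <- if (length(dim(data)) == 4) c(voxel_size_mm, tr) else voxel_size_mm
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a BIDS-style events table
#'
#' TSV with columns `onset`, `duration`, `trial_type`; trial types must be
#' `novelty`, `repetition` or `fixation`. Negative onsets, unknown labels,
#' and overlapping novelty/repetition events are rejected.
#'
#' @param path TSV file path.
#' @return Data frame of events.
#' @export
load_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    stop("events file must have columns: ", paste(need, collapse = ", "))
  if (any(ev$onset < 0)) stop("validation error: negative onset")
  if (any(ev$duration < 0)) stop("validation error: negative duration")
  known <- c("novelty", "repetition", "fixation")
  if (any(!ev$trial_type %in% known))
    stop("unknown trial_type label(s): ",
         paste(setdiff(unique(ev$trial_type), known), collapse = ", "))
  task <- ev[ev$trial_type %in% c("novelty", "repetition"), , drop = FALSE]
  if (nrow(task) > 1) {
    o <- order(task$onset)
    task <- task[o, ]
    ends <- task$onset + task$duration
    overlap <- which(task$onset[-1] < ends[-nrow(task)] - 1e-9)
    if (length(overlap)) {
      both <- task$trial_type[overlap] != task$trial_type[overlap + 1]
      if (any(both))
        stop("design error: overlapping novelty and repetition events")
    }
  }
  ev
}

#' Write an events table as BIDS-style TSV
#' @param events Data frame with `onset`, `duration`, `trial_type` (e.g.
#'   `design$events`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(events[, c("onset", "duration", "trial_type")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a confound table as TSV
#' @param confounds Data frame.
#' @param path File path.
#' @return `path` / data frame.
#' @export
write_confounds <- function(confounds, path) {
  utils::write.table(confounds, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_confounds
#' @export
read_confounds <- function(path) utils::read.delim(path)

#' Write / read a longitudinal cohort as CSV
#'
#' Long format: one row per subject visit with columns `subject`, `time`
#' (years), `outcome`, `age`, `sex` (0/1), `edu` (years), `predA` (imaging
#' predictor), `predB` (amyloid DVR), `amyloid_pos` (0/1 at the cut-off).
#'
#' @param cohort Data frame.
#' @param path File path.
#' @return `path` / data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("longitudinal_cohort", "data.frame")
  out
}

#' Echo generation parameters to a YAML sidecar
#' @param params Named list.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(params, path) {
  writeLines(yaml::as.yaml(params), path)
  invisible(path)
}
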