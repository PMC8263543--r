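#' Time-activity curve container
#'
#' A TAC holds the frame-sampled, decay-corrected radioactivity
#' concentration of one region (or voxel), in kBq/mL, on a frame schedule.
#'
#' @param schedule A `frame_schedule`.
#' @param activity Numeric vector of activity concentrations (kBq/mL),
#'   one per frame, decay-corrected to injection time.
#' @param weights Optional nonnegative per-frame fit weights (at least one
#'   positive). `NULL` means "decide at fit time".
#' @param label Region name.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, activity, weights = NULL, label = "region") {
  validate_frame_schedule(schedule)
  activity <- as.numeric(activity)
  if (length(activity) != nrow(schedule)) {
    stop("`activity` must have one value per frame (",
         nrow(schedule), " frames, got ", length(activity), ")")
  }
  if (any(!is.finite(activity))) stop("`activity` must be finite")
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != nrow(schedule)) stop("`weights` length must match frames")
    if (any(weights < 0) || all(weights == 0)) {
      stop("`weights` must be >= 0 with at least one > 0")
    }
  }
  structure(
    list(schedule = schedule, activity = activity, weights = weights,
         label = as.character(label)),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC '%s': %d frames over %.1f min, peak %.3g kBq/mL\n",
              x$label, nrow(x$schedule), max(x$schedule$frame_end) / 60,
              max(x$activity)))
  invisible(x)
}

#' Write time-activity curves to a delimited text file
#'
#' One CSV may hold several regions via the `region` column. Columns are
#' `region,frame_start_s,frame_end_s,activity_kBq_ml[,weight]`.
#'
#' @param tacs A `tac` or a list of `tac` objects sharing a schedule.
#' @param path Output file path.
#' @export
write_tacs <- function(tacs, path) {
  if (inherits(tacs, "tac")) tacs <- list(tacs)
  rows <- lapply(tacs, function(tc) {
    df <- data.frame(
      region = tc$label,
      frame_start_s = tc$schedule$frame_start,
      frame_end_s = tc$schedule$frame_end,
      activity_kBq_ml = tc$activity
    )
    if (!is.null(tc$weights)) df$weight <- tc$weights
    df
  })
  has_w <- vapply(rows, function(d) "weight" %in% names(d), logical(1))
  if (any(has_w) && !all(has_w)) {
    rows <- lapply(rows, function(d) {
      if (!"weight" %in% names(d)) d$weight <- NA_real_
      d
    })
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read time-activity curves from a delimited text file
#'
#' @param path CSV file written by [write_tacs()] (a missing `region`
#'   column is treated as a single unnamed region).
#' @return A named list of `tac` objects.
#' @export
read_tacs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_start_s", "frame_end_s", "activity_kBq_ml")
  if (!all(need %in% names(df))) {
    stop("TAC file must have columns ", paste(need, collapse = ", "))
  }
  if (!"region" %in% names(df)) df$region <- "region"
  out <- lapply(split(df, df$region), function(d) {
    d <- d[order(d$frame_start_s), ]
    sched <- data.frame(
      frame_start = d$frame_start_s,
      frame_end = d$frame_end_s,
      frame_mid = (d$frame_start_s + d$frame_end_s) / 2,
      frame_duration = d$frame_end_s - d$frame_start_s
    )
    class(sched) <- c("frame_schedule", "data.frame")
    w <- if ("weight" %in% names(d) && !all(is.na(d$weight))) d$weight else NULL
    tac(sched, d$activity_kBq_ml, weights = w, label = d$region[1])
  })
  out[unique(df$region)]
}

#' Labelled dynamic volume container
#'
#' Bundles a 4D activity array (x, y, z, frame) with a 3D integer label
#' volume (0 = background) and the frame schedule, for ROI extraction and
#' voxelwise parametric mapping.
#'
#' @param data 4D numeric array of activity concentrations (kBq/mL).
#' @param labels 3D integer array of region labels; 0 is background.
#' @param schedule A `frame_schedule` matching the 4th dimension.
#' @param region_names Named character vector or list mapping label values
#'   (as names or via `labels` attribute order) to region names, e.g.
#'   `c("1" = "pallidum")`.
#' @return An object of class `labelled_volume`.
#' @export
labelled_volume <- function(data, labels, schedule, region_names) {
  stopifnot(length(dim(data)) == 4L, length(dim(labels)) == 3L)
  if (!all(dim(data)[1:3] == dim(labels))) {
    stop("spatial dimensions of `data` and `labels` must match")
  }
  validate_frame_schedule(schedule)
  if (dim(data)[4] != nrow(schedule)) {
    stop("4th dimension of `data` must match the number of frames")
  }
  region_names <- unlist(region_names)
  if (is.null(names(region_names))) stop("`region_names` must be named by label value")
  structure(
    list(data = data, labels = labels, schedule = schedule,
         region_names = region_names),
    class = "labelled_volume"
  )
}

#' @export
print.labelled_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Labelled 4D volume: %dx%dx%d voxels x %d frames, %d regions\n",
              d[1], d[2], d[3], d[4], length(x$region_names)))
  invisible(x)
}

#' Extract region-mean time-activity curves from a labelled volume
#'
#' The ROI TAC is the arithmetic mean over all voxels carrying the region's
#' label, per frame (voxels are assumed uniform size).
#'
#' @param vol A `labelled_volume`.
#' @return A named list of `tac` objects, each with attribute `n_voxels`.
#' @export
extract_roi_tacs <- function(vol) {
  stopifnot(inherits(vol, "labelled_volume"))
  if (!any(vol$labels != 0)) stop("label volume has no nonzero labels")
  nframe <- nrow(vol$schedule)
  flat <- matrix(vol$data, ncol = nframe)  # voxel x frame
  lab_vec <- as.integer(vol$labels)
  out <- list()
  for (lab in names(vol$region_names)) {
    lv <- as.integer(lab)
    idx <- which(lab_vec == lv)
    if (length(idx) == 0L) {
      warning("label ", lv, " ('", vol$region_names[[lab]],
              "') absent from label volume; region skipped")
      next
    }
    m <- if (length(idx) == 1L) flat[idx, ] else colMeans(flat[idx, , drop = FALSE])
    tc <- tac(vol$schedule, m, label = vol$region_names[[lab]])
    attr(tc, "n_voxels") <- length(idx)
    out[[vol$region_names[[lab]]]] <- tc
  }
  out
}

#' Write / read a labelled dynamic volume as NIfTI-1 files
#'
#' The 4D activity data and the 3D integer label volume are stored as a
#' pair of NIfTI files; region names and the frame schedule travel in a
#' JSON sidecar next to the data file.
#'
#' @param vol A `labelled_volume`.
#' @param prefix Output path prefix; writes `<prefix>_pet.nii.gz`,
#'   `<prefix>_labels.nii.gz` and `<prefix>_meta.json`.
#' @export
write_volume_nifti <- function(vol, prefix) {
  stopifnot(inherits(vol, "labelled_volume"))
  RNifti::writeNifti(RNifti::asNifti(vol$data), paste0(prefix, "_pet.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(vol$labels), paste0(prefix, "_labels.nii.gz"))
  meta <- list(
    region_names = as.list(vol$region_names),
    frame_start = vol$schedule$frame_start,
    frame_end = vol$schedule$frame_end
  )
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(prefix) {
  data <- array(RNifti::readNifti(paste0(prefix, "_pet.nii.gz")),
                dim = dim(RNifti::readNifti(paste0(prefix, "_pet.nii.gz"))))
  labels <- RNifti::readNifti(paste0(prefix, "_labels.nii.gz"))
  labels <- array(as.integer(round(labels)), dim = dim(labels))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  sched <- data.frame(
    frame_start = meta$frame_start,
    frame_end = meta$frame_end,
    frame_mid = (meta$frame_start + meta$frame_end) / 2,
    frame_duration = meta$frame_end - meta$frame_start
  )
  class(sched) <- c("frame_schedule", "data.frame")
  labelled_volume(data, labels, sched, unlist(meta$region_names))
}
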