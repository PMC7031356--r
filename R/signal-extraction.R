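#' Construct a parcellation from an integer label volume
#'
#' @param label_volume 3D integer array; 0 is background, positive integers
#'   are region labels.
#' @param region_names Optional character names, one per unique label.
#' @return Object of class `parcellation` with sorted unique `region_ids`.
#' @export
parcellation <- function(label_volume, region_names = NULL) {
  if (length(dim(label_volume)) != 3L)
    stop("parcellation: label_volume must be a 3D array")
  if (any(label_volume != round(label_volume)) || any(label_volume < 0))
    stop("parcellation: labels must be non-negative integers")
  ids <- sort(unique(as.integer(label_volume)))
  ids <- ids[ids > 0L]
  if (!length(ids)) stop("parcellation: no positive labels present")
  if (!is.null(region_names) && length(region_names) != length(ids))
    stop("parcellation: region_names length must match number of regions")
  structure(list(label_volume = label_volume, region_ids = ids,
                 region_names = region_names),
            class = "parcellation")
}

#' Extract mean region time series from a 4D image
#'
#' Column j of the result is the unweighted mean, per timepoint, over all
#' voxels carrying label `region_ids[j]`; column order follows the sorted
#' region ids. NA voxels are excluded from a region's mean; a region with
#' no finite voxels is an error. Image and label volume must already be
#' voxel-aligned — no resampling is performed.
#'
#' @param image 4D array (x, y, z, t).
#' @param parc A [parcellation()] (or a bare 3D label array).
#' @param subject_id Identifier attached to the output.
#' @return A [region_ts()] with one column per region.
#' @export
extract_mean_timeseries <- function(image, parc, subject_id = "subject") {
  if (length(dim(image)) != 4L)
    stop("extract_mean_timeseries: image must be a 4D array")
  if (!inherits(parc, "parcellation")) parc <- parcellation(parc)
  if (!identical(dim(image)[1:3], dim(parc$label_volume)))
    stop("extract_mean_timeseries: spatial dimensions of image ",
         paste(dim(image)[1:3], collapse = "x"),
         " and labels ", paste(dim(parc$label_volume), collapse = "x"),
         " do not match")
  Tn <- dim(image)[4]
  nvox <- prod(dim(image)[1:3])
  mat <- matrix(image, nrow = nvox, ncol = Tn)  # voxels x time
  lab <- as.integer(parc$label_volume)
  out <- matrix(NA_real_, nrow = Tn, ncol = length(parc$region_ids))
  for (j in seq_along(parc$region_ids)) {
    rid <- parc$region_ids[j]
    rows <- which(lab == rid)
    block <- mat[rows, , drop = FALSE]
    m <- colMeans(block, na.rm = TRUE)
    if (any(!is.finite(m)))
      stop("extract_mean_timeseries: region ", rid,
           " has no finite voxels at some timepoint")
    out[, j] <- m
  }
  region_ts(subject_id, out, region_ids = sprintf("r%02d", parc$region_ids))
}

#' Extract mean time series from NIfTI files
#'
#' Convenience wrapper: reads a 4D image and a 3D integer label volume from
#' NIfTI-1 files, extracts, and optionally writes the TSV time-series
#' format (T rows, one column per region, tab-separated, with header).
#'
#' @param image_path Path to 4D `.nii`/`.nii.gz`.
#' @param labels_path Path to 3D integer label `.nii`/`.nii.gz`.
#' @param out_path Optional TSV output path.
#' @param subject_id Identifier for the output series.
#' @return The extracted [region_ts()], invisibly if `out_path` is given.
#' @export
extract_from_nifti <- function(image_path, labels_path, out_path = NULL,
                               subject_id = "subject") {
  img <- read_nifti(image_path)
  lab <- read_nifti(labels_path)
  ts <- extract_mean_timeseries(img, parcellation(lab),
                                subject_id = subject_id)
  if (!is.null(out_path)) {
    write_timeseries_tsv(ts, out_path)
    return(invisible(ts))
  }
  ts
}

#' Write a region time series as TSV (T rows x R columns, with header)
#' @param ts A [region_ts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_tsv <- function(ts, path) {
  utils::write.table(ts$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a region time series from TSV
#' @param path TSV path written by [write_timeseries_tsv()].
#' @param subject_id Identifier to attach.
#' @return A [region_ts()].
#' @export
read_timeseries_tsv <- function(path, subject_id = NULL) {
  dat <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  if (is.null(subject_id))
    subject_id <- sub("\\.tsv$", "", basename(path))
  region_ts(subject_id, as.matrix(dat), region_ids = colnames(dat))
}
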