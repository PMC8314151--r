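#' Read a 3D mask from a NIfTI file
#'
#' Loads a NIfTI volume, reorients it to the canonical RAS axis convention
#' when the header carries orientation information (so masks from
#' different sources meet on the same axes), takes voxel spacing from the
#' header, and binarizes by "nonzero is foreground" or by a specific
#' integer label.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param label optional integer: keep only voxels equal to this label.
#' @return a [binary_mask()].
#' @export
read_mask <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), "D: ", path,
         call. = FALSE)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0 || hdr$sform_code > 0)
    RNifti::orientation(img) <- "RAS"
  sp <- RNifti::pixdim(img)[1:3]
  if (anyNA(sp) || any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or invalid voxel spacing in header: ", path, call. = FALSE)
  arr <- as.array(img)
  if (is.null(label)) binary_mask(arr, sp)
  else extract_label(array(arr, dim(arr)), sp, label)
}

#' Write a mask (or labeled volume) to a NIfTI file
#'
#' @param x a [binary_mask()], or a 3D integer array with `spacing` given.
#' @param path output `.nii` or `.nii.gz` path.
#' @param spacing required when `x` is a bare array.
#' @return invisibly `path`.
#' @export
write_mask <- function(x, path, spacing = NULL) {
  if (inherits(x, "binary_mask")) {
    arr <- array(as.integer(x$grid), dim(x$grid))
    spacing <- x$spacing
  } else {
    if (is.null(spacing)) stop("spacing required for a bare array",
                               call. = FALSE)
    arr <- array(as.integer(x), dim(x))
    spacing <- grid_spacing(spacing)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label-map configuration
#'
#' JSON object mapping integer label codes (as keys) to organ names, e.g.
#' `{"1": "Brainstem", "2": "Spinal-cord"}`. Labels must be unique and
#' names must belong to [organ_taxonomy()] unless explicitly extended.
#'
#' @param path JSON file.
#' @param extra_organs additional accepted organ names beyond the default
#'   taxonomy.
#' @return named integer vector: names are organ names, values label codes.
#' @export
read_label_map <- function(path, extra_organs = character()) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- suppressWarnings(as.integer(names(obj)))
  if (anyNA(labels)) stop("label-map keys must be integers", call. = FALSE)
  if (anyDuplicated(labels)) stop("duplicate labels in label map",
                                  call. = FALSE)
  organs <- as.character(unlist(obj))
  if (anyDuplicated(organs)) stop("duplicate organ names in label map",
                                  call. = FALSE)
  known <- c(organ_taxonomy(), extra_organs)
  bad <- setdiff(organs, known)
  if (length(bad) > 0L)
    stop("unknown organ name(s): ", paste(bad, collapse = ", "),
         "; pass extra_organs to extend the taxonomy", call. = FALSE)
  stats::setNames(labels, organs)
}

#' Split a labeled volume file into per-organ masks
#'
#' @param path NIfTI file of integer labels.
#' @param label_map named integer vector from [read_label_map()].
#' @return named list of [binary_mask()], one per organ in the map.
#' @export
read_labeled_volume <- function(path, label_map) {
  masks <- lapply(label_map, function(lab) read_mask(path, label = lab))
  stats::setNames(masks, names(label_map))
}
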