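MODALITIES <- c("T1", "T1CE", "T2", "FLAIR")
MODALITY_SUFFIX <- c(T1 = "t1", T1CE = "t1ce", T2 = "t2", FLAIR = "flair")

#' Case record: file locations of one multimodal case
#'
#' @param case_id case identifier (also the folder name in the on-disk
#'   layout).
#' @param modality_paths named character vector or list mapping all four of
#'   `T1`, `T1CE`, `T2`, `FLAIR` to NIfTI file paths.
#' @param label_path optional path to the segmentation label NIfTI.
#' @return An object of class `case_record`.
#' @export
case_record <- function(case_id, modality_paths, label_path = NULL) {
  modality_paths <- as.list(modality_paths)
  missing <- setdiff(MODALITIES, names(modality_paths))
  if (length(missing) > 0L)
    stop(sprintf("case '%s' is missing modalities: %s", case_id,
                 paste(missing, collapse = ", ")), call. = FALSE)
  structure(list(case_id = case_id,
                 modality_paths = modality_paths[MODALITIES],
                 label_path = label_path),
            class = "case_record")
}

#' Discover cases under a BraTS-style directory layout
#'
#' Expects one sub-directory per case containing
#' `<case_id>_{t1,t1ce,t2,flair}.nii[.gz]` and optionally `<case_id>_seg.*`.
#'
#' @param dir dataset root directory.
#' @return A list of [case_record] objects, sorted by case id.
#' @export
find_cases <- function(dir) {
  stopifnot(dir.exists(dir))
  ids <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  lapply(ids, function(id) {
    locate <- function(suffix) {
      cands <- file.path(dir, id, paste0(id, "_", suffix,
                                         c(".nii.gz", ".nii")))
      hit <- cands[file.exists(cands)]
      if (length(hit) == 0L) NULL else hit[[1L]]
    }
    paths <- lapply(MODALITY_SUFFIX, locate)
    missing <- MODALITIES[vapply(paths, is.null, logical(1))]
    if (length(missing) > 0L)
      stop(sprintf("case '%s' is missing modalities: %s", id,
                   paste(missing, collapse = ", ")), call. = FALSE)
    case_record(id, paths, label_path = locate("seg"))
  })
}

read_nifti_array <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  array(as.numeric(a), dim = dim(a))
}

validate_label_codes <- function(labels) {
  bad <- setdiff(unique(as.vector(labels)), c(0, 1, 2, 4))
  if (length(bad) > 0L)
    stop(sprintf("unknown label codes: {%s}",
                 paste(sort(bad), collapse = ", ")), call. = FALSE)
  invisible(labels)
}

#' Read one multimodal case from disk
#'
#' @param record a [case_record].
#' @return A list with `case_id`, `channels` (named list of 3D arrays, all
#'   the same shape) and `labels` (integer 3D array or `NULL`).
#' @export
read_case <- function(record) {
  stopifnot(inherits(record, "case_record"))
  for (m in MODALITIES) {
    p <- record$modality_paths[[m]]
    if (is.null(p) || !file.exists(p))
      stop(sprintf("case '%s' is missing modalities: %s", record$case_id, m),
           call. = FALSE)
  }
  channels <- lapply(record$modality_paths, read_nifti_array)
  for (m in MODALITIES[-1L]) check_same_shape(channels[[1L]], channels[[m]])
  labels <- NULL
  if (!is.null(record$label_path)) {
    labels <- read_nifti_array(record$label_path)
    storage.mode(labels) <- "integer"
    check_same_shape(channels[[1L]], labels)
    validate_label_codes(labels)
  }
  list(case_id = record$case_id, channels = channels, labels = labels)
}

#' Write one case in BraTS-style layout
#'
#' Intensities are stored as float64 and labels as int16, so a write/read
#' round trip preserves values and label codes exactly.
#'
#' @param case a list with `case_id`, `channels`, and optionally `labels`
#'   (as from [generate_case()] or [read_case()]).
#' @param dir dataset root directory (created if needed).
#' @return The case directory path, invisibly.
#' @export
write_case <- function(case, dir) {
  stopifnot(is.list(case), !is.null(case$case_id), !is.null(case$channels))
  cdir <- file.path(dir, case$case_id)
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(case$channels)) {
    path <- file.path(cdir, sprintf("%s_%s.nii.gz", case$case_id,
                                    MODALITY_SUFFIX[[m]]))
    RNifti::writeNifti(case$channels[[m]], path, datatype = "double")
  }
  if (!is.null(case$labels)) {
    path <- file.path(cdir, sprintf("%s_seg.nii.gz", case$case_id))
    RNifti::writeNifti(case$labels, path, datatype = "int16")
  }
  invisible(cdir)
}

#' Rescale in-plane dimensions to the network input size
#'
#' Resamples the (height, width) plane of every axial slice from the native
#' acquisition size (240x240 for BraTS) down to `target_hw` (160 by default);
#' depth is unchanged. Intensity volumes use bilinear interpolation; label
#' volumes must use nearest-neighbour (`labels = TRUE`) so no new codes can
#' be fabricated.
#'
#' @param volume 3D array `(depth, height, width)` with `height == width`.
#' @param target_hw target in-plane size in pixels.
#' @param labels nearest-neighbour resampling and integer output if `TRUE`.
#' @return A 3D array `(depth, target_hw, target_hw)`.
#' @export
rescale_to_input <- function(volume, target_hw = 160, labels = FALSE) {
  check_volume(volume)
  d <- dim(volume)
  if (d[2] != d[3])
    stop("non-square in-plane input: axial slices must have height == width",
         call. = FALSE)
  stopifnot(target_hw >= 1, target_hw == round(target_hw))
  if (d[2] == target_hw) return(volume)
  planes <- aperm(volume, c(2, 3, 1))   # (H, W, depth) for in-plane resize
  res <- EBImage::resize(planes, w = target_hw, h = target_hw,
                         filter = if (labels) "none" else "bilinear")
  out <- aperm(res, c(3, 1, 2))
  out <- array(as.numeric(out), dim = c(d[1], target_hw, target_hw))
  if (labels) storage.mode(out) <- "integer"
  out
}
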