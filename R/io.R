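## Sequence I/O: multi-page TIFF (32-bit float) or NIfTI (x, y, t), plus a
## plain-text sidecar carrying pixel spacing, frame interval and t0.

sidecar_path <- function(path) paste0(path, ".meta.txt")

write_sidecar <- function(seq, path) {
  writeLines(c(sprintf("spacing_mm: %.17g %.17g", seq$spacing[1], seq$spacing[2]),
               sprintf("dt_s: %.17g", seq$dt),
               sprintf("t0_s: %.17g", seq$t0)),
             sidecar_path(path))
}

read_sidecar <- function(path) {
  f <- sidecar_path(path)
  if (!file.exists(f)) stop("sidecar metadata file not found: ", f)
  ln <- readLines(f)
  val <- function(key) {
    row <- grep(paste0("^", key, ":"), ln, value = TRUE)
    if (length(row) != 1) stop("sidecar missing key: ", key)
    as.numeric(strsplit(sub(paste0(key, ":\\s*"), "", row), "\\s+")[[1]])
  }
  list(spacing = val("spacing_mm"), dt = val("dt_s")[1], t0 = val("t0_s")[1])
}

seq_format <- function(path) {
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) "tiff"
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else stop("unsupported sequence format (use .tif/.tiff or .nii/.nii.gz): ",
            path)
}

#' Write an image sequence to disk
#'
#' Multi-page TIFF (one 32-bit float page per frame) or NIfTI (x, y, t
#' volume), chosen by file extension, plus a plain-text sidecar
#' `<path>.meta.txt` with pixel spacing (mm), frame interval (s) and t0
#' (s). TIFF pages are stored row-major with the image y axis along rows;
#' the in-memory convention (dim 1 = x) is restored on read.
#'
#' @param seq a [tag_sequence()].
#' @param path output path ending in `.tif`, `.tiff`, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "tag_sequence"))
  fmt <- seq_format(path)
  if (fmt == "tiff") {
    pages <- lapply(seq_len(n_frames(seq)), function(k) t(seq$frames[, , k]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    RNifti::writeNifti(RNifti::asNifti(seq$frames,
                                       pixdim = c(seq$spacing, seq$dt)),
                       path)
  }
  write_sidecar(seq, path)
  invisible(path)
}

#' Read an image sequence from disk
#'
#' Counterpart of [write_sequence()]; frames and metadata round-trip
#' exactly (32-bit float precision for TIFF pixel data).
#'
#' @param path path written by [write_sequence()].
#' @return A [tag_sequence()].
#' @export
read_sequence <- function(path) {
  fmt <- seq_format(path)
  meta <- read_sidecar(path)
  if (fmt == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE)
    frames <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) frames[, , k] <- t(pages[[k]])
  } else {
    img <- RNifti::readNifti(path)
    frames <- array(as.numeric(img), dim = dim(img))
    if (length(dim(frames)) == 2) frames <- array(frames, c(dim(frames), 1))
  }
  tag_sequence(frames, spacing = meta$spacing, dt = meta$dt, t0 = meta$t0)
}

#' Write a logical mask as a single-frame image
#'
#' @param mask logical matrix.
#' @param path output path (sequence formats).
#' @param spacing pixel spacing in mm.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = 1) {
  write_sequence(tag_sequence(array(mask * 1, c(dim(mask), 1)),
                              spacing = spacing, dt = 1, t0 = 0), path)
}

#' Read a logical mask written by [write_mask()]
#'
#' @param path mask path.
#' @return Logical matrix (pixel values `> 0.5`).
#' @export
read_mask <- function(path) {
  s <- read_sequence(path)
  s$frames[, , 1] > 0.5
}

#' Write ground-truth deformation and strain stacks
#'
#' Stores per-pixel tensor fields as multi-channel image stacks in the
#' sequence container (channels as pages/volumes in the documented order
#' F11, F12, F21, F22 or E11, E12, E21, E22), one file per frame set, with
#' the channel order recorded in the sidecar.
#'
#' @param tensors `2 x 2 x m` array aligned with the pixels of a
#'   `nx x ny` grid (`m = nx * ny`, column-major).
#' @param dims `c(nx, ny)`.
#' @param path output path.
#' @param spacing pixel spacing (mm).
#' @return `path`, invisibly.
#' @export
write_tensor_stack <- function(tensors, dims, path, spacing = 1) {
  stopifnot(length(dim(tensors)) == 3, all(dim(tensors)[1:2] == 2),
            dim(tensors)[3] == prod(dims))
  frames <- array(0, c(dims[1], dims[2], 4))
  ch <- 0L
  for (i in 1:2) for (j in 1:2) {
    ch <- ch + 1L
    frames[, , ch] <- matrix(tensors[i, j, ], dims[1], dims[2])
  }
  write_sequence(tag_sequence(frames, spacing = spacing, dt = 1, t0 = 0),
                 path)
  cat("channels: F11 F12 F21 F22\n", file = sidecar_path(path),
      append = TRUE)
  invisible(path)
}
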