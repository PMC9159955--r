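#' 3D image stack container
#'
#' A thin S3 wrapper around a 3D numeric array holding one imaging volume.
#' The array is indexed `[x, y, z]` with x the fast (within-scan-line) axis;
#' voxel indices are 0-based in physical terms: the centre of voxel
#' `[i, j, k]` (1-based R indices) sits at `((i-1)*vx, (j-1)*vy, (k-1)*vz)`
#' micrometres, with z = 0 the skin surface (shallowest plane).
#'
#' @param data 3D numeric array (intensities in raw counts).
#' @param voxel_size Numeric length-3, voxel pitch in µm (x, y, z). Default
#'   `c(0.427, 0.427, 1)`, the acquisition pitch of the stage-scanned
#'   two-photon setup the pipeline targets.
#' @param bit_depth 8 or 16.
#' @param session Optional session label (ordinal time point).
#' @return An `image_stack` object.
#' @export
image_stack <- function(data, voxel_size = c(0.427, 0.427, 1),
                        bit_depth = 16L, session = NA) {
  if (length(dim(data)) != 3) stopf("image_stack data must be a 3D array")
  if (any(voxel_size <= 0)) stopf("voxel sizes must be positive")
  if (!bit_depth %in% c(8L, 16L)) stopf("bit_depth must be 8 or 16")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 bit_depth = as.integer(bit_depth), session = session),
            class = "image_stack")
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d x %d voxels, %d-bit, voxel %.3f x %.3f x %.3f um, session %s\n",
              d[1], d[2], d[3], x$bit_depth, x$voxel_size[1],
              x$voxel_size[2], x$voxel_size[3], as.character(x$session)))
  invisible(x)
}

#' Physical extent of a stack in micrometres
#'
#' Extent is measured between outermost voxel centres, matching the 0-based
#' physical coordinate convention.
#'
#' @param stack An `image_stack`.
#' @return Numeric length-3 extent (µm).
#' @export
stack_extent <- function(stack) {
  (dim(stack$data) - 1) * stack$voxel_size
}

#' Write a stack as multi-page TIFF with a JSON sidecar
#'
#' One page per z-plane, 8- or 16-bit; acquisition metadata (voxel size,
#' session, seed, tile grid position) goes to `<path>.json` so a run can be
#' replayed exactly.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @param meta Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, meta = list()) {
  maxv <- if (stack$bit_depth == 16L) 65535 else 255
  pages <- lapply(seq_len(dim(stack$data)[3]), function(z) {
    t(stack$data[, , z]) / maxv
  })
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  side <- c(list(voxel_size_um = stack$voxel_size,
                 bit_depth = stack$bit_depth,
                 session = stack$session,
                 dims = dim(stack$data)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack (with optional JSON sidecar)
#'
#' @param path TIFF path written by [write_stack()] or compatible.
#' @return An `image_stack`; sidecar metadata, when present, is attached as
#'   attribute `"meta"`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stopf("stack file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- if (max(vapply(pages, max, 0)) > 255) 16L else 8L
  side_path <- paste0(path, ".json")
  voxel <- c(0.427, 0.427, 1)
  session <- NA
  meta <- NULL
  if (file.exists(side_path)) {
    meta <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    voxel <- as.numeric(meta$voxel_size_um %||% voxel)
    session <- meta$session %||% NA
    if (!is.null(meta$bit_depth)) bits <- as.integer(meta$bit_depth)
  }
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[2], d[1], length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]])
  out <- image_stack(arr, voxel_size = voxel, bit_depth = bits,
                     session = session)
  attr(out, "meta") <- meta
  out
}

#' Write a per-voxel class label volume as 8-bit multi-page TIFF
#'
#' Classes: 0 background, 1 fiber, 2 epidermal autofluorescence,
#' 3 appendage.
#'
#' @param labels 3D integer array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(labels, path) {
  pages <- lapply(seq_len(dim(labels)[3]), function(z) t(labels[, , z]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Read a label volume written by [write_label_volume()]
#' @param path TIFF path.
#' @return 3D integer array.
#' @export
read_label_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0L, dim = c(d[2], d[1], length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- as.integer(t(pages[[z]]))
  arr
}
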