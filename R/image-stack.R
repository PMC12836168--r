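#' Ordered grayscale image stack
#'
#' A time-lapse stack: ordered grayscale frames with per-frame timestamps
#' and a physical pixel size. Frames are plain numeric matrices in native
#' intensity units (`0..255` for 8-bit, `0..65535` for 16-bit).
#'
#' @param frames List of numeric matrices, all the same dimension.
#' @param timestamps_s Numeric vector of acquisition times (s), one per
#'   frame, non-decreasing.
#' @param pixel_size_um Physical pixel size (um).
#' @param bit_depth 8 or 16.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, timestamps_s, pixel_size_um, bit_depth = 8L) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop_chemotax("`frames` must be a non-empty list of matrices")
  }
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) stop_chemotax("all frames must share one shape")
  if (length(timestamps_s) != length(frames)) {
    stop_chemotax("one timestamp per frame is required")
  }
  if (any(diff(timestamps_s) < 0)) stop_chemotax("timestamps must be non-decreasing")
  if (!bit_depth %in% c(8L, 16L)) stop_chemotax("`bit_depth` must be 8 or 16")
  assert_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  structure(
    list(frames = frames, timestamps_s = as.double(timestamps_s),
         pixel_size_um = pixel_size_um, bit_depth = as.integer(bit_depth)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frame(s) of %d x %d px (%d-bit, %g um/px), t = %s s\n",
              length(x$frames), d[1], d[2], x$bit_depth, x$pixel_size_um,
              paste(utils::head(x$timestamps_s, 6), collapse = ", ")))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack An [image_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) length(stack$frames)

#' Write an image stack as a multi-page TIFF with a CSV sidecar
#'
#' Frame intensities are stored at the stack's bit depth; timestamps and the
#' pixel size go to a plain-text sidecar (`<path>.meta.csv`) so the stack
#' round-trips without binary metadata.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  maxv <- 2^stack$bit_depth - 1
  pages <- lapply(stack$frames, function(f) clamp(f / maxv, 0, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  readr::write_csv(
    tibble(frame = seq_along(stack$frames),
           t_s = stack$timestamps_s,
           pixel_size_um = stack$pixel_size_um,
           bit_depth = stack$bit_depth),
    paste0(path, ".meta.csv")
  )
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path; the `<path>.meta.csv` sidecar supplies timestamps
#'   and pixel size. Without a sidecar, `timestamps_s` and `pixel_size_um`
#'   must be given.
#' @param timestamps_s,pixel_size_um,bit_depth Metadata overrides.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, timestamps_s = NULL, pixel_size_um = NULL,
                             bit_depth = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".meta.csv")
  if (file.exists(meta_path)) {
    meta <- readr::read_csv(meta_path, show_col_types = FALSE)
    timestamps_s <- timestamps_s %||% meta$t_s
    pixel_size_um <- pixel_size_um %||% meta$pixel_size_um[1]
    bit_depth <- bit_depth %||% meta$bit_depth[1]
  }
  if (is.null(timestamps_s) || is.null(pixel_size_um)) {
    stop_chemotax("no metadata sidecar found at `%s`; supply `timestamps_s` and `pixel_size_um`",
                  meta_path)
  }
  bit_depth <- bit_depth %||% 8L
  maxv <- 2^bit_depth - 1
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    round(p * maxv)
  })
  image_stack(frames, timestamps_s, pixel_size_um, bit_depth)
}
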