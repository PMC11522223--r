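## ImageStack container and raster I/O (multi-page TIFF, numbered PNGs)

#' Construct an image stack
#'
#' @param frames numeric 3D array `[rows, cols, T]` with values in `[0, 1]`,
#'   or a list of equally-sized matrices.
#' @param pixel_size_um physical pixel pitch, um.
#' @param frame_interval_s time between frames, seconds.
#' @param provenance free-text tag recording where the stack came from.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_um, frame_interval_s = NA_real_,
                        provenance = "unknown") {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
      stopf("all frames must have the same shape")
    frames <- array(unlist(frames), c(d, length(frames)))
  }
  if (length(dim(frames)) != 3) stopf("frames must be a rows x cols x T array")
  if (pixel_size_um <= 0) stopf("pixel_size_um must be > 0")
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 provenance = provenance), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frames of %d x %d px, %.3g um/px (%s)\n",
              d[3], d[1], d[2], x$pixel_size_um, x$provenance))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]

#' Read a frame stack from a multi-page TIFF or a set of PNG files
#'
#' @param path a single TIFF path, or a character vector of PNG paths
#'   (sorted lexicographically), or a glob pattern matching PNGs.
#' @param pixel_size_um,frame_interval_s physical calibration (required;
#'   raster files do not carry it reliably).
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pixel_size_um, frame_interval_s = NA_real_) {
  if (length(path) == 1 && grepl("[*?]", path))
    path <- sort(Sys.glob(path))
  if (length(path) == 0) stopf("no input files")
  if (length(path) == 1 && grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    frames <- lapply(pages, function(p) {
      if (length(dim(p)) == 3) p <- p[, , 1]
      p
    })
  } else {
    if (!requireNamespace("png", quietly = TRUE))
      stopf("reading PNG sequences requires the 'png' package")
    frames <- lapply(path, function(f) {
      p <- png::readPNG(f)
      if (length(dim(p)) == 3) p <- p[, , 1]
      p
    })
  }
  image_stack(frames, pixel_size_um, frame_interval_s,
              provenance = paste0("file:", path[1]))
}

#' Write a stack (or binary mask stack) as a multi-page TIFF
#'
#' @param stack an [image_stack()] or a logical/numeric 3D array.
#' @param path output file.
#' @param bits_per_sample 8 or 16.
#' @export
write_stack <- function(stack, path, bits_per_sample = 16) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  storage.mode(frames) <- "double"
  pages <- lapply(seq_len(dim(frames)[3]),
                  function(i) clamp(frames[, , i], 0, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  invisible(path)
}
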