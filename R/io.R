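#' Load an image in the canonical grayscale representation
#'
#' Reads a PNG, TIFF or JPEG raster and returns a numeric matrix of
#' intensities in [0, 1], rows indexing image rows. RGB inputs are converted
#' to luminance with ITU-R BT.601 weights (0.299, 0.587, 0.114); integer
#' sample values are rescaled by the native dtype maximum (255 for 8-bit,
#' 65535 for 16-bit), matching \code{im2double} semantics. An alpha channel,
#' if present, is dropped.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @return A numeric matrix with values in [0, 1].
#' @examples
#' f <- tempfile(fileext = ".png")
#' EBImage::writeImage(EBImage::Image(matrix(0.5, 40, 40)), f)
#' img <- loadImage(f)
#' range(img)
#' @seealso [loadStack()]
#' @export
loadImage <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.bmp$", path, ignore.case = TRUE))
    stop("BMP input is not supported; convert to PNG or TIFF", call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop("cannot read image '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  a <- EBImage::imageData(img)
  if (length(a) == 0L)
    stop("zero-sized image: ", path, call. = FALSE)
  g <- .toGray(a)
  # EBImage stores x (columns) in the first dimension; transpose to rows x cols
  g <- t(g)
  if (anyNA(g) || any(g < -1e-9) || any(g > 1 + 1e-9))
    stop("image values outside [0, 1] after preparation: ", path,
         call. = FALSE)
  .clip01(g)
}

# Collapse a decoded array to a single gray channel with BT.601 weights.
.toGray <- function(a) {
  d <- dim(a)
  if (length(d) == 2L) return(a)
  if (length(d) == 3L) {
    if (d[3] %in% c(2L, 4L)) a <- a[, , -d[3], drop = FALSE]  # drop alpha
    nc <- dim(a)[3]
    if (nc == 1L) return(a[, , 1L])
    if (nc == 3L)
      return(0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L])
  }
  stop("unsupported channel layout (expect gray, gray+alpha, RGB or RGBA)",
       call. = FALSE)
}

#' Load an ordered focal stack
#'
#' Assembles a [FocalStack-class] from image files. Given a directory, all
#' PNG/TIFF/JPEG files are used in lexicographic name order; a plain-text
#' manifest (one file path per line, relative to the directory) overrides
#' the ordering. Given a character vector of paths, the given order is kept.
#'
#' @param source directory path or character vector of image paths.
#' @param manifest optional path to a manifest file fixing the frame order.
#' @return A [FocalStack-class]; frame labels are the file names.
#' @seealso [loadImage()], [writeStack()]
#' @export
loadStack <- function(source, manifest = NULL) {
  if (length(source) == 1L && dir.exists(source)) {
    if (!is.null(manifest)) {
      rel <- readLines(manifest, warn = FALSE)
      rel <- rel[nzchar(trimws(rel))]
      files <- file.path(source, trimws(rel))
    } else {
      files <- list.files(source, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                          ignore.case = TRUE, full.names = TRUE)
      files <- files[order(basename(files))]
    }
  } else {
    files <- source
  }
  if (length(files) < 3L)
    stop("a focal stack needs at least 3 frames, got ", length(files),
         call. = FALSE)
  frames <- lapply(files, loadImage)
  d <- dim(frames[[1L]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d))
      stop(sprintf(
        "frame size mismatch: '%s' is %dx%d but '%s' is %dx%d",
        basename(files[i]), nrow(frames[[i]]), ncol(frames[[i]]),
        basename(files[1L]), d[1], d[2]), call. = FALSE)
  }
  focalStack(frames, labels = basename(files))
}

#' Write a focal stack to numbered image files
#'
#' Writes each frame as PNG or TIFF plus a \code{manifest.txt} (one file name
#' per line, in frame order) so the on-disk and in-memory paths are
#' interchangeable.
#'
#' @param stack a [FocalStack-class].
#' @param dir output directory (created if missing).
#' @param format \code{"png"} or \code{"tiff"}.
#' @param bitsPerSample 8 or 16 (16 requires \code{format = "tiff"}).
#' @return Invisibly, the written file paths.
#' @seealso [loadStack()]
#' @export
writeStack <- function(stack, dir, format = c("png", "tiff"),
                       bitsPerSample = 8L) {
  format <- match.arg(format)
  stopifnot(is(stack, "FocalStack"))
  if (bitsPerSample == 16L && format != "tiff")
    stop("16-bit output requires format = 'tiff'", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "png") "png" else "tif"
  names <- sprintf("%s_%03d.%s",
                   sub("\\.[a-zA-Z]+$", "", frameLabels(stack)),
                   seq_along(frames(stack)), ext)
  paths <- file.path(dir, names)
  for (i in seq_along(paths)) {
    # transpose back to EBImage's x-major layout
    im <- EBImage::Image(t(frames(stack)[[i]]))
    if (format == "tiff")
      EBImage::writeImage(im, paths[i], type = "tiff",
                          bits.per.sample = as.integer(bitsPerSample))
    else
      EBImage::writeImage(im, paths[i], type = "png")
  }
  writeLines(names, file.path(dir, "manifest.txt"))
  invisible(paths)
}
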