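#' Read and write grayscale frames
#'
#' Frames are numeric matrices in `[0, 1]`, indexed `img[v + 1, u + 1]` with
#' 0-based pixel coordinates `(u, v)`. RGB(A) PNGs are converted to
#' luminance on read.
#'
#' @param path file path of a PNG image.
#' @return `read_frame()` returns a grayscale matrix; `write_frame()` writes
#'   the matrix and returns `path` invisibly.
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop("frame not found: ", path)
  as_gray(png::readPNG(path))
}

#' @rdname read_frame
#' @param img grayscale matrix in `[0, 1]`.
#' @export
write_frame <- function(img, path) {
  stopifnot(is.matrix(img))
  atomic_write(path, function(tmp) png::writePNG(clamp01(img), target = tmp))
  invisible(path)
}

#' Convert an image array to a grayscale matrix
#'
#' @param img a matrix (returned as is, clamped), or an `H x W x {2,3,4}`
#'   array; colour channels are combined with the Rec. 601 luminance weights.
#' @return Grayscale matrix in `[0, 1]`.
#' @export
as_gray <- function(img) {
  if (is.matrix(img)) return(clamp01(img))
  if (length(dim(img)) == 3) {
    nc <- dim(img)[3]
    if (nc >= 3)
      return(clamp01(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]))
    return(clamp01(img[, , 1]))
  }
  stop("unsupported image shape")
}

#' Pair left/right frame files by sorted name
#'
#' @param left_dir,right_dir directories containing one PNG per frame.
#' @return A data frame with columns `left` and `right` (full paths), paired
#'   in sorted filename order. Mismatched counts are an error.
#' @export
list_frame_pairs <- function(left_dir, right_dir) {
  lf <- sort(list.files(left_dir, pattern = "\\.png$", full.names = TRUE))
  rf <- sort(list.files(right_dir, pattern = "\\.png$", full.names = TRUE))
  if (length(lf) == 0) stop("no PNG frames in ", left_dir)
  if (length(lf) != length(rf))
    stop("left/right frame counts differ: ", length(lf), " vs ", length(rf))
  data.frame(left = lf, right = rf, stringsAsFactors = FALSE)
}
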