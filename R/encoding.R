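#' Encode pixel brightness as spike times
#'
#' Latency coding: salient pixels spike early. With `invert = TRUE` (the
#' convention for datasets where salient strokes are bright), brightness v in
#' `[0, 1]` becomes the encoded value 1 - v, which is the spike time; encoded
#' values equal to 1 (white) carry no information and become [NO_SPIKE].
#' With `invert = FALSE` the pixel value is used as the spike time directly
#' (value-1 pixels still emit no spike).
#'
#' @param image numeric vector or matrix of pixel values in `[0, 1]`
#'   (1 = white background).
#' @param invert invert brightness before encoding (default `TRUE`).
#' @return spike-time vector (shape preserved), entries in `[0, 1]` or
#'   [NO_SPIKE].
#' @examples
#' encode_image(c(1, 0.9, 0))   # spikes at 0 and 0.1; white -> NO_SPIKE
#' @export
encode_image <- function(image, invert = TRUE) {
  v <- as.numeric(image)
  if (any(!is.finite(v)) || any(v < 0 | v > 1)) {
    stop("pixel values must be finite and in [0, 1]")
  }
  enc <- if (invert) 1 - v else v
  enc[enc >= 1] <- NO_SPIKE
  if (!is.null(dim(image))) dim(enc) <- dim(image)
  enc
}

#' Clipped-Gaussian noise on encoded spike times
#'
#' Each encoded value t becomes `max(0, min(t + eta * r, 1))` with
#' `r ~ Normal(r_mean, 1)` drawn independently per pixel. [NO_SPIKE] entries
#' are represented as the value 1 before noising, so with `r_mean = 1` (the
#' convention for inverted-brightness encoding, pushing noise toward the
#' uninformative end) they stay white almost surely, while negative
#' excursions can create spurious early spikes. Results equal to 1 map back
#' to [NO_SPIKE].
#'
#' @param encoded spike-time vector/matrix with values in `[0, 1]` or
#'   [NO_SPIKE].
#' @param eta non-negative noise factor; `eta = 0` returns the input
#'   unchanged.
#' @param r_mean mean of the noise variable (1 for inverted-brightness
#'   encoding, 0 otherwise).
#' @param seed optional integer seed for reproducible noise.
#' @return noisy spike-time object of the same shape.
#' @export
add_noise <- function(encoded, eta, r_mean = 1, seed = NULL) {
  if (eta < 0) stop("`eta` must be non-negative")
  v <- as.numeric(encoded)
  v[!is.finite(v)] <- 1
  if (any(v < 0 | v > 1)) stop("encoded values must be in [0, 1]")
  if (eta > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    r <- rnorm(length(v), mean = r_mean, sd = 1)
    v <- pmax(0, pmin(v + eta * r, 1))
  }
  v[v >= 1] <- NO_SPIKE
  if (!is.null(dim(encoded))) dim(v) <- dim(encoded)
  v
}

#' Decode output spike times back to pixel values
#'
#' Inverts the latency target map: an output spike at time t decodes to the
#' encoded value `clamp(t - l, 0, 1)`; [NO_SPIKE] decodes to 1 (no
#' information). With `invert = TRUE` the brightness inversion is undone for
#' display.
#'
#' @param output spike-time vector/matrix from the network's output layer.
#' @param l target latency used in training.
#' @param invert undo the brightness inversion (must match the encoding).
#' @return pixel values in `[0, 1]`, same shape as `output`.
#' @export
decode_spikes <- function(output, l, invert = TRUE) {
  t <- as.numeric(output)
  v <- pmin(pmax(t - l, 0), 1)
  v[!is.finite(t)] <- 1
  if (invert) v <- 1 - v
  if (!is.null(dim(output))) dim(v) <- dim(output)
  v
}

#' Read an IDX image or label file
#'
#' The IDX container (as used by the MNIST/FMNIST distributions): big-endian
#' magic number (0x00000803 for image tensors, 0x00000801 for label
#' vectors), dimension sizes, then unsigned bytes. Image bytes are scaled to
#' `[0, 1]` by /255.
#'
#' @param path IDX file path.
#' @return for images, a list with `pixels` (matrix, one row per image, one
#'   column per pixel in row-major order) and `dim` (c(n, rows, cols));
#'   for labels, an integer vector.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic == 0x00000803L) {
    d <- readBin(con, "integer", 3, size = 4, endian = "big")
    raw <- readBin(con, "integer", prod(d), size = 1, signed = FALSE)
    px <- matrix(raw / 255, nrow = d[1], ncol = d[2] * d[3], byrow = TRUE)
    list(pixels = px, dim = d)
  } else if (magic == 0x00000801L) {
    n <- readBin(con, "integer", 1, size = 4, endian = "big")
    as.integer(readBin(con, "integer", n, size = 1, signed = FALSE))
  } else {
    stop("not an IDX image/label file (magic ", magic, "): ", path)
  }
}

#' Write images or labels in IDX format
#'
#' Counterpart of [read_idx]; pixel values in `[0, 1]` are quantised to
#' unsigned bytes.
#'
#' @param x for images, a matrix with one row per image (row-major pixels);
#'   for labels, an integer vector.
#' @param path output file path.
#' @param dim for images, c(rows, cols) of each image; inferred as square if
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_idx <- function(x, path, dim = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (is.matrix(x)) {
    n <- nrow(x)
    if (is.null(dim)) {
      side <- sqrt(ncol(x))
      if (side != round(side)) stop("`dim` required for non-square images")
      dim <- c(side, side)
    }
    writeBin(0x00000803L, con, size = 4, endian = "big")
    writeBin(as.integer(c(n, dim)), con, size = 4, endian = "big")
    bytes <- as.integer(round(pmin(pmax(t(x), 0), 1) * 255))
    writeBin(as.raw(bytes), con)
  } else {
    writeBin(0x00000801L, con, size = 4, endian = "big")
    writeBin(length(x), con, size = 4, endian = "big")
    writeBin(as.raw(as.integer(x)), con)
  }
  invisible(path)
}
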