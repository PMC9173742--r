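#' Profile line across an image
#'
#' Defines the sampling band for a medial-lateral innervation profile: a
#' straight line from a midline point to the lateral terminus (in practice,
#' the end of the medial lemniscus), sampled with a band of `thickness`
#' pixels perpendicular to the line — the line-tool-with-thickness
#' convention of interactive image analysis.
#'
#' @param start,end Numeric length-2 pixel coordinates `(row, col)`,
#'   1-based; `start` is the midline end.
#' @param thickness Band width in pixels (>= 1).
#' @return A `profile_line` list.
#' @export
profile_line <- function(start, end, thickness = 100L) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 2L || length(end) != 2L)
    stop("start and end must be (row, col) pairs")
  if (all(start == end)) stop("start and end must differ")
  if (thickness < 1L) stop("thickness must be >= 1")
  structure(list(start = start, end = end, thickness = as.integer(thickness)),
            class = "profile_line")
}

# Bilinear interpolation of image values at fractional (row, col) positions;
# positions outside the image raise an error.
.bilinear <- function(img, r, c) {
  nr <- nrow(img)
  nc <- ncol(img)
  if (any(r < 1 | r > nr | c < 1 | c > nc))
    stop("profile line (with its band) exits the image")
  r0 <- pmin(floor(r), nr - 1L)
  c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0
  fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Extract a band-averaged intensity profile along a line
#'
#' Samples the image at unit arc-length steps along the line; at each step
#' the intensity is the mean of `thickness` bilinear samples spaced one
#' pixel apart along the perpendicular, centered on the line. Intensities
#' are used as-is (convert images to [0, 1] floats before calling).
#'
#' @param image Numeric matrix (rows x cols grayscale image).
#' @param line A `profile_line` lying, with its band, inside the image.
#' @return Numeric vector of band-averaged intensities, one per arc-length
#'   step from `start` (midline) to `end` (lateral terminus).
#' @export
extract_band_profile <- function(image, line) {
  stopifnot(inherits(line, "profile_line"))
  delta <- line$end - line$start
  len <- sqrt(sum(delta^2))
  u <- delta / len                      # unit vector along the line
  v <- c(-u[2], u[1])                   # unit perpendicular
  n_steps <- floor(len) + 1L            # unit arc-length sampling
  t_along <- seq(0, len, length.out = n_steps)
  offs <- seq_len(line$thickness) - (line$thickness + 1) / 2
  vapply(t_along, function(tt) {
    p <- line$start + tt * u
    mean(.bilinear(image, p[1] + offs * v[1], p[2] + offs * v[2]))
  }, numeric(1))
}

#' Resample a raw profile into a fixed number of bins
#'
#' Partitions the samples into `n_bins` contiguous, near-equal index ranges
#' and averages within each. When the raw profile is shorter than `n_bins`
#' it is first up-sampled by linear interpolation so every bin is defined.
#'
#' @param raw Numeric vector of intensities along the line.
#' @param n_bins Number of output bins (default 100).
#' @return Numeric vector of length `n_bins`.
#' @export
bin_profile <- function(raw, n_bins = 100L) {
  n <- length(raw)
  if (n == 0L) stop("empty profile")
  if (n < n_bins)
    raw <- stats::approx(seq_len(n), raw, n = n_bins)$y
  n <- length(raw)
  # bin j takes samples i with (j-1)n/n_bins < i <= jn/n_bins, i.e.
  # j = ceiling(i * n_bins / n), in exact integer arithmetic
  idx <- factor((seq_len(n) * n_bins + n - 1L) %/% n,
                levels = seq_len(n_bins))
  as.numeric(tapply(raw, idx, mean))
}

#' Normalize a binned profile to its maximum
#'
#' Divides by the maximum so the profile peaks at exactly 1 — the image-level
#' normalization that makes profiles comparable across images with different
#' exposure.
#'
#' @param binned Numeric vector with positive maximum.
#' @param level Profile level label.
#' @return An `innervation_profile`: the normalized vector with `level` and
#'   `n_averaged` attributes.
#' @export
normalize_profile <- function(binned, level = "image") {
  m <- max(binned)
  if (m <= 0) stop("cannot normalize an all-zero profile")
  structure(binned / m, level = level, n_averaged = 1L,
            class = "innervation_profile")
}

#' Average profiles up one level of the hierarchy
#'
#' Element-wise mean of equal-length profiles. The reporting hierarchy is
#' images -> brain -> region -> cluster; image-level profiles peak at 1,
#' averaged levels peak at <= 1.
#'
#' @param profiles List of numeric vectors of equal length.
#' @param level_out Level label of the averaged profile.
#' @return An `innervation_profile`.
#' @export
average_profiles <- function(profiles, level_out = "brain") {
  if (length(profiles) == 0L) stop("no profiles to average")
  lens <- lengths(profiles)
  if (length(unique(lens)) != 1L) stop("profiles differ in length")
  avg <- Reduce(`+`, lapply(profiles, as.numeric)) / length(profiles)
  structure(avg, level = level_out, n_averaged = length(profiles),
            class = "innervation_profile")
}

#' @export
print.innervation_profile <- function(x, ...) {
  cat(sprintf("<innervation_profile> %d bins, level %s (n = %d), peak %.3f\n",
              length(x), attr(x, "level"), attr(x, "n_averaged"), max(x)))
  invisible(x)
}

#' Full image-to-profile pipeline for one image
#'
#' @param image Numeric matrix.
#' @param line A `profile_line`.
#' @param n_bins Number of bins (default 100).
#' @return An image-level `innervation_profile` of length `n_bins`.
#' @export
image_profile <- function(image, line, n_bins = 100L) {
  normalize_profile(bin_profile(extract_band_profile(image, line), n_bins))
}

#' Read / write grayscale images
#'
#' PNG I/O for profile images. Images are converted to a numeric matrix in
#' [0, 1] on read (color images are averaged over channels); on write,
#' intensities are clipped to [0, 1].
#'
#' @param path PNG file path.
#' @return `read_gray_image`: numeric matrix in [0, 1].
#' @export
read_gray_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:3, drop = FALSE], c(1, 2), mean)
  a
}

#' @rdname read_gray_image
#' @param image Numeric matrix.
#' @export
write_gray_image <- function(image, path) {
  png::writePNG(pmax(pmin(image, 1), 0), path)
  invisible(path)
}
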