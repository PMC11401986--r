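#' Six-parameter affine intensity normalization transform
#'
#' Constructs the affine transform Illumina-style genotyping applies to raw
#' two-channel intensities before genotype calling: translation (offsets),
#' rotation, shear removal and per-axis scaling. Each GTC file carries one or
#' more of these; every record points at the transform that applies to it.
#'
#' @param offset_x,offset_y Translation in raw-intensity units.
#' @param theta Rotation angle in radians.
#' @param shear Dimensionless shear removed from the first coordinate.
#' @param scale_x,scale_y Strictly positive per-axis scale divisors.
#' @return A one-row `data.frame` with columns `version`, `offset_x`,
#'   `offset_y`, `theta`, `shear`, `scale_x`, `scale_y`. Several transforms
#'   are represented by row-binding such frames.
#' @seealso [apply_normalization()], [invert_normalization()]
#' @export
#' @examples
#' normalization_transform()                     # identity
#' normalization_transform(offset_x = 10, theta = 0.05, scale_x = 1.2)
normalization_transform <- function(offset_x = 0, offset_y = 0, theta = 0,
                                    shear = 0, scale_x = 1, scale_y = 1) {
  if (!is.numeric(scale_x) || !is.numeric(scale_y) ||
      any(scale_x <= 0) || any(scale_y <= 0))
    abort_parameter("scale_x and scale_y must be strictly positive")
  data.frame(version = 1L,
             offset_x = as.numeric(offset_x), offset_y = as.numeric(offset_y),
             theta = as.numeric(theta), shear = as.numeric(shear),
             scale_x = as.numeric(scale_x), scale_y = as.numeric(scale_y))
}

#' Apply the affine normalization to raw intensities
#'
#' Runs the four stages in the vendor reference order: subtract the offsets,
#' rotate by `theta`, remove the shear from the first coordinate, divide by
#' the per-axis scales. Negative results are clamped to zero so downstream
#' log transforms stay defined.
#'
#' @param x_raw,y_raw Numeric vectors of raw channel intensities.
#' @param transform A single transform as returned by
#'   [normalization_transform()] (a one-row data frame or a list with the same
#'   fields).
#' @return A list with numeric vectors `x` and `y` (normalized intensities,
#'   non-negative).
#' @export
#' @examples
#' apply_normalization(100, 50, normalization_transform())            # identity
#' apply_normalization(100, 50, normalization_transform(10, 5))       # offsets
apply_normalization <- function(x_raw, y_raw, transform) {
  t <- as.list(transform)
  if (length(t$scale_x) != 1L || length(t$scale_y) != 1L ||
      !is.finite(t$scale_x) || !is.finite(t$scale_y) ||
      t$scale_x <= 0 || t$scale_y <= 0)
    abort_parameter("normalization transform requires strictly positive scales")
  tx <- x_raw - t$offset_x
  ty <- y_raw - t$offset_y
  rx <- cos(t$theta) * tx + sin(t$theta) * ty
  ry <- -sin(t$theta) * tx + cos(t$theta) * ty
  rx <- rx - t$shear * ry
  list(x = pmax(rx / t$scale_x, 0), y = pmax(ry / t$scale_y, 0))
}

#' Invert the affine normalization
#'
#' Algebraic inverse of [apply_normalization()] without the clamp: maps
#' normalized intensities back to raw channel intensities. Used by the
#' simulator to manufacture raw intensities that normalize onto a target
#' point, and by invertibility checks.
#'
#' @inheritParams apply_normalization
#' @param x,y Numeric vectors of normalized intensities.
#' @return A list with numeric vectors `x_raw` and `y_raw`.
#' @export
invert_normalization <- function(x, y, transform) {
  t <- as.list(transform)
  if (t$scale_x <= 0 || t$scale_y <= 0)
    abort_parameter("normalization transform requires strictly positive scales")
  rx <- x * t$scale_x
  ry <- y * t$scale_y
  rx <- rx + t$shear * ry
  tx <- cos(t$theta) * rx - sin(t$theta) * ry
  ty <- sin(t$theta) * rx + cos(t$theta) * ry
  list(x_raw = tx + t$offset_x, y_raw = ty + t$offset_y)
}
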