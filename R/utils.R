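# Shared grid helpers.  Image convention: matrices with row 1 at the top of
# the image; physical x (mm) increases with column, y increases upward.
# Pixel centres: x = (col - (n+1)/2) * h, y = ((n+1)/2 - row) * h.

grid_axis <- function(n, h) (seq_len(n) - (n + 1) / 2) * h

#' Physical pixel-centre coordinates of an image grid
#'
#' @param shape integer vector `c(rows, cols)`.
#' @param pixel_mm isotropic pixel size in mm.
#' @return list with matrices `x` and `y` (mm), same shape as the image.
#' @keywords internal
grid_coords <- function(shape, pixel_mm) {
  nr <- shape[1]; nc <- shape[2]
  x <- matrix(grid_axis(nc, pixel_mm), nr, nc, byrow = TRUE)
  y <- matrix(rev(grid_axis(nr, pixel_mm)), nr, nc)
  list(x = x, y = y)
}

# row/col of the pixel whose centre is closest to physical (x, y)
phys_to_rc <- function(x, y, shape, pixel_mm) {
  col <- round(x / pixel_mm + (shape[2] + 1) / 2)
  row <- round((shape[1] + 1) / 2 - y / pixel_mm)
  c(row, col)
}

rc_to_phys <- function(row, col, shape, pixel_mm) {
  c(x = (col - (shape[2] + 1) / 2) * pixel_mm,
    y = ((shape[1] + 1) / 2 - row) * pixel_mm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

min_to_s <- function(t) t * 60
s_to_min <- function(t) t / 60

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    rlang::abort(sprintf("`%s` must be a single positive number", name))
}
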