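# Digital 2D thorax phantom: label map, tissue property table, geometry.
#
# The phantom is a single coronal plane holding the structures that matter
# for cardiac perfusion imaging: a myocardial ring (left ventricle) with LV
# and RV blood pools, lungs, liver, soft-tissue body background, and a
# non-transmural perfusion defect embedded in the outer part of the
# mid-anterolateral wall (about 4 mm across the wall and 12 mm along it).

#' Default tissue property table
#'
#' One row per tissue label: one-tissue-compartment kinetics (`K1`
#' mL/min/mL, `k2` 1/min), 511-keV linear attenuation (`mu`, 1/mm), and MR
#' properties at 3 T (`pd` proton-density fraction of water, `t1`/`t2` ms).
#' The myocardium and defect kinetics and MR values are the study's
#' generating truth; the remaining tissues are configurable stand-ins with
#' physiologically reasonable values. Blood-pool rows carry a `blood` tag
#' ("lv"/"rv"): their activity follows the arterial input function rather
#' than a compartment curve.
#'
#' @return A tibble with columns `label`, `name`, `K1`, `k2`, `mu`, `pd`,
#'   `t1`, `t2`, `blood`.
#' @export
tissue_properties <- function() {
  tibble::tribble(
    ~label, ~name,          ~K1,  ~k2,  ~mu,    ~pd,  ~t1,  ~t2,  ~blood,
    0L,     "air",          0,    0,    0,      0,    0,    0,    NA,
    1L,     "soft_tissue",  0.05, 0.50, 0.0096, 0.80, 900,  50,   NA,
    2L,     "lung",         0.12, 0.90, 0.0029, 0.25, 1200, 30,   NA,
    3L,     "liver",        0.60, 0.80, 0.0098, 0.70, 800,  42,   NA,
    4L,     "lv_blood",     0,    0,    0.0097, 0.90, 1550, 275,  "lv",
    5L,     "rv_blood",     0,    0,    0.0097, 0.90, 1550, 275,  "rv",
    6L,     "myocardium",   0.80, 0.17, 0.0097, 0.67, 830,  62,   NA,
    7L,     "defect",       0.36, 0.21, 0.0097, 0.77, 1080, 82,   NA
  )
}

#' Phantom configuration
#'
#' Geometry of the synthetic thorax in physical units. All shapes are
#' analytic (ellipses / annulus / angular sector) rasterized onto the pixel
#' grid; coordinates are mm with the grid centre at the origin, x to the
#' right, y upward (superior).
#'
#' @param grid_n grid size in pixels (square grid).
#' @param pixel_mm isotropic pixel size, mm.
#' @param slice_mm slice thickness, mm (used for ROI volumes).
#' @param heart_center mm, centre of the LV.
#' @param wall_radii mm, inner/outer radius of the myocardial ring.
#' @param defect_thickness_mm through-wall extent of the defect (from the
#'   epicardial surface inward); 0 disables the defect.
#' @param defect_length_mm along-wall extent at mid-defect radius.
#' @param defect_angle_deg angular position of the defect centre
#'   (anatomical anterolateral wall by default).
#' @param properties tissue property table, see [tissue_properties()].
#' @return A list of class `"phantom_config"`.
#' @export
phantom_config <- function(grid_n = 128L, pixel_mm = 3, slice_mm = 3,
                           heart_center = c(30, 40),
                           wall_radii = c(12, 22),
                           defect_thickness_mm = 4,
                           defect_length_mm = 12,
                           defect_angle_deg = 135,
                           properties = tissue_properties()) {
  stopifnot_scalar_pos(grid_n, "grid_n")
  stopifnot_scalar_pos(pixel_mm, "pixel_mm")
  cfg <- list(grid_n = as.integer(grid_n), pixel_mm = pixel_mm,
              slice_mm = slice_mm, heart_center = heart_center,
              wall_radii = wall_radii,
              defect_thickness_mm = defect_thickness_mm,
              defect_length_mm = defect_length_mm,
              defect_angle_deg = defect_angle_deg,
              body_semiaxes = c(140, 175),
              lung_centers = list(c(-72, 60), c(78, 55)),
              lung_semiaxes = c(45, 80),
              liver_center = c(-52, -70), liver_semiaxes = c(70, 50),
              rv_center_offset = c(-26, -6), rv_radius = 8,
              properties = properties)
  class(cfg) <- "phantom_config"
  cfg
}

#' Build the digital thorax phantom
#'
#' Rasterizes the configured anatomy into a tissue label map and validates
#' that the defect fits inside the myocardial wall. The defect occupies the
#' outer `defect_thickness_mm` of the wall over an arc of
#' `defect_length_mm` at mid-defect radius, so it is non-transmural by
#' construction.
#'
#' @param config a [phantom_config()].
#' @return An object of class `"phantom"`: `label_map` (integer matrix),
#'   `properties` (tibble), `grid_shape`, `pixel_size`, `slice_thickness`,
#'   `lv_center` (row/col) and `lv_center_mm` (x/y), plus the config.
#' @export
build_phantom <- function(config = phantom_config()) {
  n <- config$grid_n; h <- config$pixel_mm
  ri <- config$wall_radii[1]; ro <- config$wall_radii[2]
  dth <- config$defect_thickness_mm; dlen <- config$defect_length_mm
  if (dth > (ro - ri))
    rlang::abort(sprintf(
      "defect does not fit inside the myocardial wall: through-wall thickness %.1f mm exceeds wall thickness %.1f mm",
      dth, ro - ri))
  rmid <- ro - dth / 2
  if (dth > 0 && dlen > 2 * pi * rmid)
    rlang::abort(sprintf(
      "defect does not fit inside the myocardial wall: along-wall length %.1f mm exceeds circumference %.1f mm",
      dlen, 2 * pi * rmid))

  xy <- grid_coords(c(n, n), h)
  x <- xy$x; y <- xy$y
  lab <- matrix(0L, n, n)

  in_ellipse <- function(cen, ax) ((x - cen[1]) / ax[1])^2 + ((y - cen[2]) / ax[2])^2 <= 1
  lab[in_ellipse(c(0, 0), config$body_semiaxes)] <- 1L
  for (lc in config$lung_centers) lab[in_ellipse(lc, config$lung_semiaxes) & lab == 1L] <- 2L
  lab[in_ellipse(config$liver_center, config$liver_semiaxes) & lab != 0L] <- 3L

  hc <- config$heart_center
  rvc <- hc + config$rv_center_offset
  rr <- sqrt((x - hc[1])^2 + (y - hc[2])^2)
  rv <- sqrt((x - rvc[1])^2 + (y - rvc[2])^2) <= config$rv_radius
  lab[rv & lab != 0L] <- 5L
  lab[rr <= ro & rr > ri & lab != 0L] <- 6L
  lab[rr <= ri & lab != 0L] <- 4L

  if (dth > 0 && dlen > 0) {
    half_arc <- (dlen / 2) / rmid
    ang <- atan2(y - hc[2], x - hc[1])
    dang <- abs(((ang - config$defect_angle_deg * pi / 180 + pi) %% (2 * pi)) - pi)
    lab[lab == 6L & rr > (ro - dth) & dang <= half_arc] <- 7L
  }

  props <- config$properties
  present <- sort(unique(as.vector(lab)))
  if (!all(present %in% props$label))
    rlang::abort("label map contains labels with no property row")
  props <- props[props$label %in% present, , drop = FALSE]

  lvc_mm <- hc
  lvc_rc <- phys_to_rc(hc[1], hc[2], c(n, n), h)
  structure(list(label_map = lab, properties = props,
                 grid_shape = c(n, n), pixel_size = h,
                 slice_thickness = config$slice_mm,
                 lv_center = lvc_rc, lv_center_mm = lvc_mm,
                 config = config),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %dx%d grid, %.1f mm pixels, %d tissue classes\n",
              x$grid_shape[1], x$grid_shape[2], x$pixel_size,
              nrow(x$properties)))
  counts <- table(factor(x$label_map, levels = x$properties$label))
  for (i in seq_len(nrow(x$properties)))
    cat(sprintf("  %d %-12s %6d px\n", x$properties$label[i],
                x$properties$name[i], counts[i]))
  invisible(x)
}

#' Look up a per-pixel property map from the label map
#'
#' @param phantom a [build_phantom()] object.
#' @param kind one of `"mu"`, `"pd"`, `"t1"`, `"t2"`, `"label"`.
#' @return a numeric (or integer for `"label"`) matrix.
#' @export
property_map <- function(phantom, kind = c("mu", "pd", "t1", "t2", "label")) {
  kind <- match.arg(kind)
  if (kind == "label") return(phantom$label_map)
  vals <- setNames(phantom$properties[[kind]], phantom$properties$label)
  m <- matrix(vals[as.character(phantom$label_map)],
              phantom$grid_shape[1], phantom$grid_shape[2])
  m[is.na(m)] <- 0
  m
}

#' Per-pixel activity map from per-tissue concentrations
#'
#' @param phantom a phantom.
#' @param tissue_values named numeric vector, names are tissue labels;
#'   missing labels get 0 (air always 0).
#' @return numeric matrix of activity concentration.
#' @export
activity_map <- function(phantom, tissue_values) {
  v <- tissue_values[as.character(phantom$label_map)]
  v[is.na(v)] <- 0
  matrix(v, phantom$grid_shape[1], phantom$grid_shape[2])
}

#' Measure the pixelated extents of the defect region
#'
#' Through-wall extent is the radial span of defect pixel centres plus one
#' pixel; along-wall extent is the angular span times the mid-defect radius
#' plus one pixel.
#'
#' @param phantom a phantom.
#' @return named numeric vector `c(through_wall_mm, along_wall_mm)`, zeros
#'   if no defect is present.
#' @export
defect_extents <- function(phantom) {
  idx <- which(phantom$label_map == 7L)
  if (!length(idx)) return(c(through_wall_mm = 0, along_wall_mm = 0))
  xy <- grid_coords(phantom$grid_shape, phantom$pixel_size)
  hc <- phantom$lv_center_mm
  dx <- xy$x[idx] - hc[1]; dy <- xy$y[idx] - hc[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  a0 <- phantom$config$defect_angle_deg * pi / 180
  dang <- ((ang - a0 + pi) %% (2 * pi)) - pi
  c(through_wall_mm = diff(range(r)) + phantom$pixel_size,
    along_wall_mm = diff(range(dang)) * mean(r) + phantom$pixel_size)
}
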