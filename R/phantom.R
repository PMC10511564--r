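# Digital liver-slice phantom: a parenchyma disc containing one lesion
# (optionally with a necrotic core) and optional vessels, rasterized on a
# pixel-center grid (0-based indices, row-major; a pixel belongs to a disc
# iff its center is inside).

LBL_BACKGROUND <- 0L
LBL_PARENCHYMA <- 1L
LBL_LESION     <- 2L
LBL_NECROSIS   <- 3L
LBL_VESSEL     <- 4L

#' Phantom specification
#'
#' Geometric and tissue-parameter description of a synthetic single-slice
#' liver phantom: a circular parenchyma region on a background, one lesion
#' disc, an optional concentric necrotic core, and optional vessel discs.
#' The default grid mirrors the acquisition (256 x 256 over a 400 mm FOV,
#' 1.5625 mm pixels).
#'
#' @param matrix_size Grid dimensions, c(rows, cols).
#' @param pixel_mm Pixel spacing in mm.
#' @param lesion_center_px Lesion center, 0-based c(row, col) pixel coords
#'   (default: grid center).
#' @param lesion_diameter_mm Lesion diameter (mm); must cover >= 2 pixels.
#' @param necrosis_diameter_mm Necrotic-core diameter (mm); 0 for none.
#'   The core is concentric with the lesion.
#' @param parenchyma_radius_px Radius of the parenchyma disc, centered on the
#'   grid (default 45\% of the smaller grid dimension).
#' @param vessels List of vessel discs, each \code{list(center_px, radius_px)}.
#' @param t1_liver_ms,t1_lesion_ms,t1_necrosis_ms,t1_vessel_ms Compartment
#'   T1 values (ms).
#' @param m0_liver,m0_lesion,m0_necrosis,m0_vessel Compartment equilibrium
#'   signals (arbitrary units).
#' @return An object of class \code{"phantom_spec"}.
#' @seealso \code{\link{render_phantom}}, \code{\link{lesion_phantom}}
#' @export
phantom_spec <- function(matrix_size = c(256L, 256L),
                         pixel_mm = 400 / 256,
                         lesion_center_px = (matrix_size - 1) / 2,
                         lesion_diameter_mm = 19.1,
                         necrosis_diameter_mm = 0,
                         parenchyma_radius_px = 0.45 * min(matrix_size),
                         vessels = list(),
                         t1_liver_ms = 654, t1_lesion_ms = 1187,
                         t1_necrosis_ms = 1687, t1_vessel_ms = 1584,
                         m0_liver = 1, m0_lesion = 1,
                         m0_necrosis = 1, m0_vessel = 1) {
  stopifnot(length(matrix_size) == 2L, all(matrix_size >= 16),
            pixel_mm > 0, lesion_diameter_mm > 0, necrosis_diameter_mm >= 0,
            parenchyma_radius_px > 0,
            t1_liver_ms > 0, t1_lesion_ms > 0, t1_necrosis_ms > 0,
            t1_vessel_ms > 0, m0_liver > 0, m0_lesion > 0)
  if (lesion_diameter_mm / pixel_mm < 2)
    stop("lesion must span at least 2 pixels at the configured spacing")
  if (necrosis_diameter_mm > lesion_diameter_mm)
    stop("necrotic core cannot be larger than the lesion")
  structure(list(matrix_size = as.integer(matrix_size), pixel_mm = pixel_mm,
                 lesion_center_px = as.numeric(lesion_center_px),
                 lesion_diameter_mm = lesion_diameter_mm,
                 necrosis_diameter_mm = necrosis_diameter_mm,
                 parenchyma_radius_px = parenchyma_radius_px,
                 vessels = vessels,
                 t1 = c(liver = t1_liver_ms, lesion = t1_lesion_ms,
                        necrosis = t1_necrosis_ms, vessel = t1_vessel_ms),
                 m0 = c(liver = m0_liver, lesion = m0_lesion,
                        necrosis = m0_necrosis, vessel = m0_vessel)),
            class = "phantom_spec")
}

# squared distance of every pixel center to a point (0-based row/col)
pixel_dist2 <- function(matrix_size, center) {
  dr <- (seq_len(matrix_size[1]) - 1) - center[1]
  dc <- (seq_len(matrix_size[2]) - 1) - center[2]
  outer(dr^2, dc^2, "+")
}

#' Render a phantom to label, T1 and M0 maps
#'
#' Rasterizes a \code{\link{phantom_spec}} on its pixel grid.  Labels are
#' 0 background, 1 parenchyma, 2 lesion, 3 necrosis, 4 vessel, and partition
#' the grid.  Geometry is validated analytically: the lesion disc must lie
#' wholly inside the parenchyma disc, the necrotic core inside the lesion,
#' and vessels inside the parenchyma without touching the lesion.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return An object of class \code{"phantom"}: list with integer
#'   \code{label_map}, numeric \code{t1_map} (ms; NA on background),
#'   \code{m0_map} (0 on background), and the \code{spec}.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ms <- spec$matrix_size
  ctr <- (ms - 1) / 2
  r_par <- spec$parenchyma_radius_px
  r_les <- spec$lesion_diameter_mm / 2 / spec$pixel_mm
  r_nec <- spec$necrosis_diameter_mm / 2 / spec$pixel_mm

  d_lc <- sqrt(sum((spec$lesion_center_px - ctr)^2))
  if (d_lc + r_les > r_par)
    stop("lesion does not fit inside the parenchyma region")

  lbl <- matrix(LBL_BACKGROUND, ms[1], ms[2])
  lbl[pixel_dist2(ms, ctr) <= r_par^2] <- LBL_PARENCHYMA

  d2_les <- pixel_dist2(ms, spec$lesion_center_px)
  lbl[d2_les <= r_les^2] <- LBL_LESION
  if (r_nec > 0) lbl[d2_les <= r_nec^2] <- LBL_NECROSIS

  for (v in spec$vessels) {
    dv <- sqrt(sum((v$center_px - ctr)^2))
    if (dv + v$radius_px > r_par)
      stop("vessel does not fit inside the parenchyma region")
    if (sqrt(sum((v$center_px - spec$lesion_center_px)^2)) <= v$radius_px + r_les)
      stop("vessel overlaps the lesion")
    lbl[pixel_dist2(ms, v$center_px) <= v$radius_px^2] <- LBL_VESSEL
  }

  t1 <- matrix(NA_real_, ms[1], ms[2])
  m0 <- matrix(0, ms[1], ms[2])
  for (i in seq_along(c("liver", "lesion", "necrosis", "vessel"))) {
    name <- c("liver", "lesion", "necrosis", "vessel")[i]
    sel <- lbl == i
    t1[sel] <- spec$t1[[name]]
    m0[sel] <- spec$m0[[name]]
  }

  structure(list(label_map = lbl, t1_map = t1, m0_map = m0, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  tab <- table(factor(x$label_map, levels = 0:4,
                      labels = c("background", "parenchyma", "lesion",
                                 "necrosis", "vessel")))
  cat(sprintf("Liver-slice phantom %d x %d (%.4g mm/px)\n",
              nrow(x$label_map), ncol(x$label_map), x$spec$pixel_mm))
  print(tab)
  invisible(x)
}

#' Build a phantom from one cohort lesion
#'
#' Translates one row of a \code{\link{sample_cohort}} table into a rendered
#' phantom: lesion diameter and compartment T1 values come from the cohort
#' draw, the lesion sits at the grid center, a concentric necrotic core is
#' added when the cohort row carries one, and two small vessels are placed
#' at fixed polar positions in the parenchyma.
#'
#' @param lesion One-row data.frame from \code{\link{sample_cohort}}.
#' @param matrix_size Grid dimensions (default 128 x 128; the acquisition
#'   FOV/matrix ratio fixes the pixel size, so a smaller grid crops the
#'   field of view without changing geometry).
#' @param pixel_mm Pixel spacing (mm).
#' @param n_vessels Number of vessel discs (0, 1 or 2).
#' @return A rendered \code{phantom} (see \code{\link{render_phantom}}).
#' @export
lesion_phantom <- function(lesion, matrix_size = c(128L, 128L),
                           pixel_mm = 400 / 256, n_vessels = 2L) {
  stopifnot(is.data.frame(lesion), nrow(lesion) == 1L, n_vessels %in% 0:2)
  ms <- as.integer(matrix_size)
  ctr <- (ms - 1) / 2
  # integer-pixel lesion center so that small lesions keep a pixel after
  # the ROI rule's 1-pixel erosion margin
  ctr_les <- floor(ctr)
  r_par <- 0.45 * min(ms)
  vr <- 2.5
  ang <- c(0.25, 1.25) * pi
  vrad <- 0.75 * r_par
  vessels <- lapply(seq_len(n_vessels), function(i) {
    list(center_px = ctr + vrad * c(sin(ang[i]), cos(ang[i])), radius_px = vr)
  })
  spec <- phantom_spec(
    matrix_size = ms, pixel_mm = pixel_mm,
    lesion_center_px = ctr_les,
    lesion_diameter_mm = lesion$diameter_mm,
    necrosis_diameter_mm = if (isTRUE(lesion$has_necrosis))
      lesion$necrosis_diameter_mm else 0,
    parenchyma_radius_px = r_par,
    vessels = vessels,
    t1_liver_ms = lesion$t1_liver_ms,
    t1_lesion_ms = lesion$t1_lesion_ms,
    t1_necrosis_ms = lesion$t1_lesion_ms + 500,
    m0_lesion = lesion$m0_ratio,
    m0_necrosis = lesion$m0_ratio)
  render_phantom(spec)
}
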