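# Deterministic, auditable replacements for the study's manual ROI rules:
# "as large as possible" becomes the largest inscribed pixel-center disc
# after a 1-pixel erosion margin; the parenchyma ROI has the same radius
# and sits at the nearest valid parenchyma location.

# Euclidean distance of each pixel in `sel` (logical matrix) to the nearest
# pixel NOT in `sel`, treating outside-grid as not-in-set.  Brute force
# against the complement restricted to the expanded bounding box of `sel`.
dist_to_complement <- function(sel) {
  nr <- nrow(sel); nc <- ncol(sel)
  idx <- which(sel)
  if (length(idx) == 0L) return(numeric(0))
  r <- (idx - 1L) %% nr          # 0-based row
  c <- (idx - 1L) %/% nr         # 0-based col
  r0 <- max(0L, min(r) - 1L); r1 <- min(nr - 1L, max(r) + 1L)
  c0 <- max(0L, min(c) - 1L); c1 <- min(nc - 1L, max(c) + 1L)
  box_r <- rep(r0:r1, times = c1 - c0 + 1L)
  box_c <- rep(c0:c1, each = r1 - r0 + 1L)
  box_idx <- box_c * nr + box_r + 1L
  comp <- !sel[box_idx]
  qr <- box_r[comp]; qc <- box_c[comp]
  # distance to nearest outside-grid pixel center (virtual ring at -1 / n)
  d_edge <- pmin(r + 1L, nr - r, c + 1L, nc - c)
  if (length(qr) == 0L) return(as.numeric(d_edge))
  d2 <- outer(r, qr, function(a, b) (a - b)^2) +
    outer(c, qc, function(a, b) (a - b)^2)
  pmin(sqrt(apply(d2, 1L, min)), d_edge)
}

# largest inscribed pixel-center disc (integer radius) in logical set `sel`;
# ties toward smallest (row, col).  Returns center (0-based) and radius, or
# NULL if the set is empty.
largest_inscribed_disc <- function(sel) {
  idx <- which(sel)
  if (length(idx) == 0L) return(NULL)
  d <- dist_to_complement(sel)
  r_int <- ceiling(d) - 1               # largest integer radius < d
  nr <- nrow(sel)
  rr <- (idx - 1L) %% nr
  cc <- (idx - 1L) %/% nr
  ord <- order(-r_int, rr, cc)
  best <- ord[1L]
  list(center_px = c(rr[best], cc[best]), radius_px = r_int[best])
}

disc_pixels <- function(dim, center, radius) {
  r0 <- center[1]; c0 <- center[2]
  dr <- seq.int(floor(r0 - radius), ceiling(r0 + radius))
  dc <- seq.int(floor(c0 - radius), ceiling(c0 + radius))
  dr <- dr[dr >= 0 & dr < dim[1]]
  dc <- dc[dc >= 0 & dc < dim[2]]
  g <- expand.grid(r = dr, c = dc)
  keep <- (g$r - r0)^2 + (g$c - c0)^2 <= radius^2 + 1e-9
  as.integer(g$c[keep] * dim[1] + g$r[keep] + 1L)
}

roi_sample <- function(compartment, pixels, center_px, radius_px) {
  structure(list(compartment = compartment, pixels = pixels,
                 center_px = center_px, radius_px = radius_px,
                 n = length(pixels)),
            class = "roi_sample")
}

#' @export
print.roi_sample <- function(x, ...) {
  cat(sprintf("%s ROI: disc radius %g px at (%g, %g), %d pixels\n",
              x$compartment, x$radius_px, x$center_px[1], x$center_px[2],
              x$n))
  invisible(x)
}

#' Place lesion and parenchyma ROIs on a label map
#'
#' Deterministic operationalization of the study's manual ROI protocol.
#' The lesion ROI is the largest inscribed pixel-center disc (integer
#' radius) in the viable lesion (lesion minus necrosis) after a 1-pixel
#' erosion margin, ties broken toward the smallest (row, col) center.  The
#' parenchyma ROI is a disc of identical radius at the parenchyma pixel
#' nearest to the lesion boundary whose disc contains parenchyma only (no
#' lesion, necrosis, vessel or background), same tie-break.  Both ROIs are
#' placed once per label map and reused across every condition of a series.
#'
#' @param label_map Integer matrix with labels 0 background, 1 parenchyma,
#'   2 lesion, 3 necrosis, 4 vessel (or a rendered \code{phantom} /
#'   \code{ir_series}, whose label map is used).
#' @param min_area Minimum number of eligible lesion pixels (default 5).
#' @return List with elements \code{lesion} and \code{parenchyma}, each a
#'   \code{roi_sample} (pixel index set, center, radius).
#' @export
place_rois <- function(label_map, min_area = 5L) {
  if (inherits(label_map, "phantom")) label_map <- label_map$label_map
  if (inherits(label_map, "ir_series")) label_map <- label_map$label_map
  stopifnot(is.matrix(label_map))
  dm <- dim(label_map)

  eligible <- label_map == LBL_LESION
  if (sum(eligible) < min_area)
    stop(sprintf("lesion too small: %d eligible pixels < min_area %d",
                 sum(eligible), min_area))
  # 1-pixel erosion margin
  d <- dist_to_complement(eligible)
  eroded <- eligible
  eroded[which(eligible)] <- d > 1
  disc <- largest_inscribed_disc(eroded)
  if (is.null(disc))
    stop("lesion too small: nothing remains after the 1-pixel erosion margin")
  les_pix <- disc_pixels(dm, disc$center_px, disc$radius_px)
  stopifnot(all(label_map[les_pix] == LBL_LESION))
  lesion_roi <- roi_sample("lesion", les_pix, disc$center_px, disc$radius_px)

  # parenchyma candidates: nearest to the lesion boundary, disc all-parenchyma
  par_idx <- which(label_map == LBL_PARENCHYMA)
  if (length(par_idx) == 0L) stop("no parenchyma pixels in label map")
  les_idx <- which(label_map %in% c(LBL_LESION, LBL_NECROSIS))
  nr <- dm[1]
  pr <- (par_idx - 1L) %% nr; pc <- (par_idx - 1L) %/% nr
  # boundary of the lesion: lesion pixels with a non-lesion 4-neighbour
  lr <- (les_idx - 1L) %% nr; lc <- (les_idx - 1L) %/% nr
  in_les <- matrix(FALSE, dm[1], dm[2]); in_les[les_idx] <- TRUE
  nb <- function(dr, dc) {
    r2 <- lr + dr; c2 <- lc + dc
    out <- r2 < 0 | r2 >= dm[1] | c2 < 0 | c2 >= dm[2]
    res <- rep(TRUE, length(lr))
    res[!out] <- !in_les[c2[!out] * nr + r2[!out] + 1L]
    res
  }
  on_bd <- nb(1L, 0L) | nb(-1L, 0L) | nb(0L, 1L) | nb(0L, -1L)
  br <- lr[on_bd]; bc <- lc[on_bd]
  d_les <- sqrt(apply(outer(pr, br, function(a, b) (a - b)^2) +
                        outer(pc, bc, function(a, b) (a - b)^2), 1L, min))

  rad <- disc$radius_px
  cand <- which(d_les > rad)                  # disc would hit the lesion else
  ord <- cand[order(d_les[cand], pr[cand], pc[cand])]
  for (i in ord) {
    ctr <- c(pr[i], pc[i])
    if (ctr[1] - rad < 0 || ctr[1] + rad > dm[1] - 1 ||
        ctr[2] - rad < 0 || ctr[2] + rad > dm[2] - 1) next
    pix <- disc_pixels(dm, ctr, rad)
    if (all(label_map[pix] == LBL_PARENCHYMA)) {
      return(list(lesion = lesion_roi,
                  parenchyma = roi_sample("parenchyma", pix, ctr, rad)))
    }
  }
  stop("no valid parenchyma ROI placement for the required radius")
}

#' Mean signal intensity in an ROI
#'
#' @param image Numeric matrix.
#' @param roi A \code{roi_sample} from \code{\link{place_rois}} (or an
#'   integer vector of pixel indices).
#' @return Arithmetic mean of the pixel values in the ROI.
#' @export
measure_si <- function(image, roi) {
  stopifnot(is.matrix(image))
  pix <- if (inherits(roi, "roi_sample")) roi$pixels else as.integer(roi)
  if (length(pix) == 0L) stop("ROI is empty")
  if (any(pix < 1L) || any(pix > length(image)))
    stop("ROI contains out-of-bounds pixels")
  mean(image[pix])
}

#' Lesion-to-liver contrast
#'
#' The study's contrast statistic
#' \deqn{LLC = \left|\frac{SI_{liver} - SI_{lesion}}{SI_{liver}}\right|,}
#' dimensionless and invariant under common positive scaling of both
#' signals.  Undefined when the liver signal is exactly zero (possible only
#' in noise-free simulation at the parenchyma null TI); that case raises a
#' classed error (\code{ircontrast_undefined_contrast}) which the cohort
#' table builder converts into a missing-with-reason record.
#'
#' @param si_liver Mean liver signal (> 0).
#' @param si_lesion Mean lesion signal (>= 0).
#' @return The LLC value (>= 0).
#' @examples
#' llc(100, 70)  # 0.3
#' @export
llc <- function(si_liver, si_lesion) {
  stopifnot(is.numeric(si_liver), is.numeric(si_lesion),
            length(si_liver) == length(si_lesion))
  if (any(si_liver < 0) || any(si_lesion < 0))
    stop("signal intensities must be >= 0")
  if (any(si_liver == 0))
    stop(structure(class = c("ircontrast_undefined_contrast", "error",
                             "condition"),
                   list(message = "LLC undefined: SI_liver is zero",
                        call = sys.call(-1))))
  abs(si_liver - si_lesion) / si_liver
}
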