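#' Synthetic cohort configuration
#'
#' Describes the statistical structure of the simulated study population:
#' how many lesions, their tumour-entity mix, the per-entity truncated-normal
#' distributions of lesion and parenchyma T1, and the lesion-diameter
#' distribution.  Defaults reproduce the cohort the package emulates:
#' 44 patients with 51 lesions (20 colorectal metastases, 12 HCC, 9 melanoma,
#' 5 breast, 2 neuroendocrine, 1 pancreatic, 1 cholangiocarcinoma, 1 uveal
#' melanoma), lesion T1 1187 +/- 456 ms overall (HCC 1063 +/- 381,
#' CRC 1319 +/- 545), parenchyma T1 654 +/- 96 ms overall (HCC patients
#' 712 +/- 115, CRC patients 609 +/- 69), and diameters on [6, 41] mm with
#' mean 19.1 mm.
#'
#' T1 distributions are truncated symmetrically about their mean (at
#' min(3, 0.99 mean/SD) SDs) so the configured mean is the exact truncated
#' mean and all draws are positive.  The diameter distribution is truncated
#' to its hard range and the parent mean is calibrated numerically so the
#' truncated mean equals \code{diameter_mean_mm} exactly.
#'
#' @param n_lesions Total number of lesions.
#' @param entity_mix Named integer vector of lesion counts per entity; must
#'   sum to \code{n_lesions}.  Entities without a specific T1 entry use the
#'   overall distributions.
#' @param patients_per_entity Named integer vector of patient counts per
#'   entity (each <= the lesion count; extra lesions are assigned round-robin
#'   within the entity).  Entities absent from this vector get one patient
#'   per lesion.
#' @param lesion_t1 Named list of \code{c(mean, sd)} (ms); must contain
#'   \code{"default"}; may contain per-entity entries (defaults: HCC, CRC).
#' @param liver_t1 Same structure for the parenchyma T1 of a patient, keyed
#'   by the patient's entity.
#' @param diameter_mean_mm,diameter_sd_mm,diameter_range_mm Lesion-diameter
#'   truncated normal: target mean, parent SD, and hard range (mm).
#' @param necrosis_prob Probability that a lesion carries a necrotic core.
#' @param necrosis_min_diameter_mm Lesions below this diameter never carry
#'   necrosis (small metastases rarely show macroscopic necrosis, and a core
#'   in a tiny lesion leaves no viable rim for an ROI).
#' @param necrosis_frac Necrotic-core diameter as a fraction of the lesion
#'   diameter.
#' @param necrosis_t1_offset_ms Added to the lesion T1 for necrotic tissue
#'   (necrosis is T1-longer than viable tumour).
#' @param m0_ratio Lesion:parenchyma equilibrium-signal ratio (point mass).
#' @param seed Integer seed controlling all cohort sampling.
#' @return An object of class \code{"cohort_config"}.
#' @seealso \code{\link{sample_cohort}}
#' @export
cohort_config <- function(n_lesions = 51L,
                          entity_mix = c(CRC = 20L, HCC = 12L, melanoma = 9L,
                                         breast = 5L, NET = 2L,
                                         pancreatic = 1L, CCC = 1L,
                                         uveal = 1L),
                          patients_per_entity = c(CRC = 15L, HCC = 12L,
                                                  melanoma = 9L, breast = 3L,
                                                  NET = 2L, pancreatic = 1L,
                                                  CCC = 1L, uveal = 1L),
                          lesion_t1 = list(default = c(1187, 456),
                                           HCC = c(1063, 381),
                                           CRC = c(1319, 545)),
                          liver_t1 = list(default = c(654, 96),
                                          HCC = c(712, 115),
                                          CRC = c(609, 69)),
                          diameter_mean_mm = 19.1,
                          diameter_sd_mm = 8,
                          diameter_range_mm = c(6, 41),
                          necrosis_prob = 0.2,
                          necrosis_min_diameter_mm = 15,
                          necrosis_frac = 0.4,
                          necrosis_t1_offset_ms = 500,
                          m0_ratio = 1.0,
                          seed = 1L) {
  n_lesions <- as.integer(n_lesions)
  if (is.null(names(entity_mix)) || any(!nzchar(names(entity_mix))))
    stop("'entity_mix' must be a named vector")
  if (sum(entity_mix) != n_lesions)
    stop(sprintf("entity_mix sums to %d but n_lesions is %d",
                 sum(entity_mix), n_lesions))
  if (!"default" %in% names(lesion_t1) || !"default" %in% names(liver_t1))
    stop("lesion_t1 and liver_t1 need a 'default' entry")
  for (d in c(lesion_t1, liver_t1))
    if (length(d) != 2L || d[2] <= 0 || d[1] <= 0)
      stop("T1 distributions must be c(mean, sd) with both > 0")
  stopifnot(diameter_range_mm[1] < diameter_mean_mm,
            diameter_mean_mm < diameter_range_mm[2],
            diameter_sd_mm > 0,
            necrosis_prob >= 0, necrosis_prob <= 1,
            necrosis_min_diameter_mm >= 0,
            necrosis_frac > 0, necrosis_frac < 1,
            m0_ratio > 0)
  structure(list(n_lesions = n_lesions,
                 entity_mix = entity_mix,
                 patients_per_entity = patients_per_entity,
                 lesion_t1 = lesion_t1,
                 liver_t1 = liver_t1,
                 diameter_mean_mm = diameter_mean_mm,
                 diameter_sd_mm = diameter_sd_mm,
                 diameter_range_mm = diameter_range_mm,
                 necrosis_prob = necrosis_prob,
                 necrosis_min_diameter_mm = necrosis_min_diameter_mm,
                 necrosis_frac = necrosis_frac,
                 necrosis_t1_offset_ms = necrosis_t1_offset_ms,
                 m0_ratio = m0_ratio,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d lesions, %d entities, seed %d\n",
              x$n_lesions, length(x$entity_mix), x$seed))
  cat("  entity mix:",
      paste(sprintf("%s=%d", names(x$entity_mix), x$entity_mix),
            collapse = ", "), "\n")
  cat(sprintf("  lesion T1 default %g +/- %g ms; liver T1 default %g +/- %g ms\n",
              x$lesion_t1$default[1], x$lesion_t1$default[2],
              x$liver_t1$default[1], x$liver_t1$default[2]))
  cat(sprintf("  diameters %g mm mean on [%g, %g] mm\n",
              x$diameter_mean_mm, x$diameter_range_mm[1],
              x$diameter_range_mm[2]))
  invisible(x)
}

dist_for <- function(dists, entity) {
  if (!is.null(dists[[entity]])) dists[[entity]] else dists$default
}

#' Sample a synthetic lesion cohort
#'
#' Draws a reproducible cohort of patients and lesions: entity counts match
#' the configured mix exactly, lesion T1 and diameters are drawn from the
#' configured truncated normals, and each patient's parenchyma T1 is sampled
#' once (from the entity-specific distribution where one exists) and shared
#' across that patient's lesions.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return A data.frame with one row per lesion and columns
#'   \code{patient_id}, \code{lesion_id}, \code{entity}, \code{diameter_mm},
#'   \code{t1_lesion_ms}, \code{t1_liver_ms}, \code{has_necrosis},
#'   \code{necrosis_diameter_mm}, \code{m0_ratio}, \code{seed}.
#' @examples
#' coh <- sample_cohort(cohort_config(seed = 7))
#' table(coh$entity)
#' @export
sample_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(config$seed, "cohort"))

  entities <- names(config$entity_mix)
  rows <- list()
  patient_counter <- 0L
  lesion_counter <- 0L

  for (ent in entities) {
    n_les <- as.integer(config$entity_mix[[ent]])
    if (n_les == 0L) next
    n_pat <- config$patients_per_entity[[ent]]
    if (is.null(n_pat) || is.na(n_pat)) n_pat <- n_les
    n_pat <- min(as.integer(n_pat), n_les)
    # round-robin: lesion j belongs to patient ((j - 1) mod n_pat) + 1
    pat_of_lesion <- ((seq_len(n_les) - 1L) %% n_pat) + 1L

    lt <- dist_for(config$liver_t1, ent)
    lb <- t1_trunc_bounds(lt[1], lt[2])
    liver_t1_pat <- rtnorm(n_pat, lt[1], lt[2], lb[1], lb[2])

    kt <- dist_for(config$lesion_t1, ent)
    kb <- t1_trunc_bounds(kt[1], kt[2])
    lesion_t1 <- rtnorm(n_les, kt[1], kt[2], kb[1], kb[2])

    mu_d <- calibrate_tnorm_mu(config$diameter_mean_mm, config$diameter_sd_mm,
                               config$diameter_range_mm[1],
                               config$diameter_range_mm[2])
    diam <- rtnorm(n_les, mu_d, config$diameter_sd_mm,
                   config$diameter_range_mm[1], config$diameter_range_mm[2])

    has_nec <- runif(n_les) < config$necrosis_prob &
      diam >= config$necrosis_min_diameter_mm

    rows[[ent]] <- data.frame(
      patient_id = patient_counter + pat_of_lesion,
      lesion_id = lesion_counter + seq_len(n_les),
      entity = ent,
      diameter_mm = diam,
      t1_lesion_ms = lesion_t1,
      t1_liver_ms = liver_t1_pat[pat_of_lesion],
      has_necrosis = has_nec,
      necrosis_diameter_mm = ifelse(has_nec, config$necrosis_frac * diam, 0),
      m0_ratio = config$m0_ratio,
      stringsAsFactors = FALSE)
    patient_counter <- patient_counter + n_pat
    lesion_counter <- lesion_counter + n_les
  }

  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$seed <- config$seed
  stopifnot(all(out$t1_lesion_ms > 0), all(out$t1_liver_ms > 0),
            all(out$diameter_mm >= config$diameter_range_mm[1]),
            all(out$diameter_mm <= config$diameter_range_mm[2]))
  out
}
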