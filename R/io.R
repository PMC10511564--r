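# File interfaces: NIfTI image series with JSON sidecars, cohort and
# contrast tables as CSV, stats reports as JSON, run configuration as YAML.

#' Write / read a simulated image series as NIfTI
#'
#' The TI stack is stored as one 4D float32 NIfTI volume
#' (rows x cols x 1 x n_TI) with a JSON sidecar carrying the acquisition
#' metadata (TI list, noise sigma, kappa, B/A, seed); the label map is an
#' integer NIfTI; the VIBE comparator, when present, its own volume.
#' \code{read_series} reconstructs the \code{ir_series}; a sidecar whose TI
#' list does not match the number of stored volumes is a format error.
#'
#' @param series An \code{ir_series} from \code{\link{simulate_series}}.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, e.g. \code{"lesion-3"}.
#' @return \code{write_series}: invisible character vector of file paths;
#'   \code{read_series}: an \code{ir_series}.
#' @export
write_series <- function(series, dir, prefix) {
  stopifnot(inherits(series, "ir_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f_ir <- file.path(dir, paste0(prefix, "_ir.nii.gz"))
  f_lab <- file.path(dir, paste0(prefix, "_labels.nii.gz"))
  f_json <- file.path(dir, paste0(prefix, "_ir.json"))
  dm <- dim(series$images)
  arr <- array(series$images, dim = c(dm[1], dm[2], 1L, dm[3]))
  RNifti::writeNifti(arr, f_ir, datatype = "float")
  RNifti::writeNifti(series$label_map, f_lab, datatype = "int16")
  meta <- list(ti_list_ms = series$ti_ms,
               noise_sigma = series$acq$noise_sigma,
               kappa = series$acq$kappa,
               b_over_a = series$acq$b_over_a,
               include_vibe = !is.null(series$vibe),
               vibe_tr_ms = series$acq$vibe$tr_ms,
               vibe_flip_deg = series$acq$vibe$flip_deg,
               seed = series$seed)
  jsonlite::write_json(meta, f_json, auto_unbox = TRUE, digits = NA)
  files <- c(f_ir, f_lab, f_json)
  if (!is.null(series$vibe)) {
    f_vibe <- file.path(dir, paste0(prefix, "_vibe.nii.gz"))
    RNifti::writeNifti(series$vibe, f_vibe, datatype = "float")
    files <- c(files, f_vibe)
  }
  invisible(files)
}

#' @rdname write_series
#' @export
read_series <- function(dir, prefix) {
  f_ir <- file.path(dir, paste0(prefix, "_ir.nii.gz"))
  f_lab <- file.path(dir, paste0(prefix, "_labels.nii.gz"))
  f_json <- file.path(dir, paste0(prefix, "_ir.json"))
  for (f in c(f_ir, f_lab, f_json))
    if (!file.exists(f)) stop("missing file: ", f)
  meta <- jsonlite::read_json(f_json, simplifyVector = TRUE)
  arr <- as.array(RNifti::readNifti(f_ir))
  dm <- dim(arr)
  if (length(dm) == 4L) arr <- array(arr, dim = dm[c(1, 2, 4)])
  if (dim(arr)[3] != length(meta$ti_list_ms))
    stop(sprintf("format error: sidecar lists %d TIs but series has %d volumes",
                 length(meta$ti_list_ms), dim(arr)[3]))
  lab <- matrix(as.integer(as.array(RNifti::readNifti(f_lab))),
                dm[1], dm[2])
  vibe <- NULL
  f_vibe <- file.path(dir, paste0(prefix, "_vibe.nii.gz"))
  if (isTRUE(meta$include_vibe)) {
    if (!file.exists(f_vibe))
      stop("sidecar declares a VIBE volume but ", f_vibe, " is missing")
    vibe <- matrix(as.array(RNifti::readNifti(f_vibe)), dm[1], dm[2])
  }
  acq <- acquisition_spec(ti_list_ms = meta$ti_list_ms,
                          noise_sigma = meta$noise_sigma,
                          kappa = meta$kappa, b_over_a = meta$b_over_a,
                          include_vibe = isTRUE(meta$include_vibe),
                          vibe = spgr_params(meta$vibe_tr_ms,
                                             meta$vibe_flip_deg))
  structure(list(images = arr, ti_ms = meta$ti_list_ms, vibe = vibe,
                 label_map = lab, acq = acq,
                 seed = as.integer(meta$seed)),
            class = "ir_series")
}

known_config_keys <- list(
  cohort = c("n_lesions", "entity_mix", "patients_per_entity", "lesion_t1",
             "liver_t1", "diameter_mean_mm", "diameter_sd_mm",
             "diameter_range_mm", "necrosis_prob", "necrosis_frac",
             "necrosis_t1_offset_ms", "m0_ratio"),
  acquisition = c("ti_list_ms", "noise_sigma", "kappa", "b_over_a",
                  "include_vibe", "vibe_tr_ms", "vibe_flip_deg"),
  simulate = c("matrix_size", "n_vessels"),
  top = c("cohort", "acquisition", "simulate", "seed"))

#' Read and validate a run configuration from YAML
#'
#' The YAML mirrors the constructor arguments: top-level blocks
#' \code{cohort}, \code{acquisition}, \code{simulate} plus a global
#' \code{seed}.  Unknown keys are rejected with their key path.
#'
#' @param path YAML file path.
#' @return List with \code{config} (a \code{\link{cohort_config}}),
#'   \code{acq} (an \code{\link{acquisition_spec}}), \code{matrix_size},
#'   and \code{seed}.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("schema error: top level must be a mapping")
  bad <- setdiff(names(raw), known_config_keys$top)
  if (length(bad)) stop("schema error: unknown key(s): ",
                        paste(bad, collapse = ", "))
  for (blk in c("cohort", "acquisition", "simulate")) {
    if (is.null(raw[[blk]])) next
    bad <- setdiff(names(raw[[blk]]), known_config_keys[[blk]])
    if (length(bad))
      stop("schema error: unknown key(s): ",
           paste(paste0(blk, ".", bad), collapse = ", "))
  }
  seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  ca <- raw$cohort
  if (!is.null(ca$entity_mix)) ca$entity_mix <- unlist(ca$entity_mix)
  if (!is.null(ca$patients_per_entity))
    ca$patients_per_entity <- unlist(ca$patients_per_entity)
  for (f in c("lesion_t1", "liver_t1"))
    if (!is.null(ca[[f]])) ca[[f]] <- lapply(ca[[f]], unlist)
  config <- do.call(cohort_config, c(ca, list(seed = seed)))
  aa <- raw$acquisition
  if (!is.null(aa)) {
    vibe <- spgr_params(tr_ms = if (is.null(aa$vibe_tr_ms)) 3.5
                                else aa$vibe_tr_ms,
                        flip_deg = if (is.null(aa$vibe_flip_deg)) 10
                                   else aa$vibe_flip_deg)
    aa$vibe_tr_ms <- aa$vibe_flip_deg <- NULL
    if (!is.null(aa$ti_list_ms)) aa$ti_list_ms <- unlist(aa$ti_list_ms)
    acq <- do.call(acquisition_spec, c(aa, list(vibe = vibe)))
  } else acq <- acquisition_spec()
  matrix_size <- if (!is.null(raw$simulate$matrix_size))
    rep_len(unlist(raw$simulate$matrix_size), 2L) else c(128L, 128L)
  list(config = config, acq = acq, matrix_size = matrix_size, seed = seed)
}

#' Simulate a cohort to disk
#'
#' Samples the cohort, renders and simulates every lesion's series, and
#' writes: \code{cohort.csv}, per-lesion NIfTI series/label maps with JSON
#' sidecars, and a resolved copy of the configuration
#' (\code{resolved_config.yaml}).  Deterministic for a fixed seed.
#'
#' @param config A \code{\link{cohort_config}}, or the path to a YAML run
#'   configuration (see \code{\link{read_run_config}}).
#' @param out_dir Output directory.
#' @param acq An \code{\link{acquisition_spec}} (ignored when \code{config}
#'   is a YAML path).
#' @param matrix_size Phantom grid.
#' @param seed Global seed (default: the config's).
#' @return Invisible list: cohort data.frame and written file paths.
#' @export
run_simulate <- function(config = cohort_config(), out_dir,
                         acq = acquisition_spec(),
                         matrix_size = c(128L, 128L), seed = NULL) {
  if (is.character(config)) {
    rc <- read_run_config(config)
    config <- rc$config; acq <- rc$acq; matrix_size <- rc$matrix_size
    if (is.null(seed)) seed <- rc$seed
  }
  if (is.null(seed)) seed <- config$seed
  config$seed <- as.integer(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  cohort <- sample_cohort(config)
  files <- character(0)
  for (i in seq_len(nrow(cohort))) {
    lesion <- cohort[i, , drop = FALSE]
    ph <- lesion_phantom(lesion, matrix_size = matrix_size)
    ser <- simulate_series(ph, acq,
                           seed = derive_seed(seed,
                                              paste0("lesion-",
                                                     lesion$lesion_id)))
    files <- c(files,
               write_series(ser, out_dir,
                            sprintf("lesion-%03d", lesion$lesion_id)))
  }
  f_cohort <- file.path(out_dir, "cohort.csv")
  write.csv(cohort, f_cohort, row.names = FALSE)
  f_cfg <- file.path(out_dir, "resolved_config.yaml")
  yaml::write_yaml(list(
    cohort = list(n_lesions = config$n_lesions,
                  entity_mix = as.list(config$entity_mix),
                  diameter_mean_mm = config$diameter_mean_mm,
                  diameter_sd_mm = config$diameter_sd_mm,
                  necrosis_prob = config$necrosis_prob,
                  m0_ratio = config$m0_ratio),
    acquisition = list(ti_list_ms = acq$ti_list_ms,
                       noise_sigma = acq$noise_sigma, kappa = acq$kappa,
                       b_over_a = acq$b_over_a,
                       include_vibe = acq$include_vibe,
                       vibe_tr_ms = acq$vibe$tr_ms,
                       vibe_flip_deg = acq$vibe$flip_deg),
    simulate = list(matrix_size = as.integer(matrix_size)),
    seed = as.integer(seed)), f_cfg)
  invisible(list(cohort = cohort, files = c(files, f_cohort, f_cfg)))
}

#' Analyse a simulated (or user-supplied) cohort directory
#'
#' Reads \code{cohort.csv} and each lesion's series, builds the contrast
#' table, fits ROI-level T1 per compartment, runs the statistical battery,
#' and writes \code{contrast_table.csv}, \code{t1_summary.csv},
#' \code{stats.json} and a plain-text report table.
#'
#' @param in_dir Directory produced by \code{\link{run_simulate}}.
#' @param out_dir Output directory (default: \code{in_dir}).
#' @return Invisible list with the \code{cohort_table}, the augmented
#'   cohort (fitted T1 columns), and the \code{llc_battery}.
#' @export
run_analyze <- function(in_dir, out_dir = in_dir) {
  f_cohort <- file.path(in_dir, "cohort.csv")
  if (!file.exists(f_cohort)) stop("missing cohort.csv in ", in_dir)
  cohort <- read.csv(f_cohort, stringsAsFactors = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  recs <- vector("list", nrow(cohort))
  t1_les <- t1_liv <- rep(NA_real_, nrow(cohort))
  conds <- NULL
  for (i in seq_len(nrow(cohort))) {
    prefix <- sprintf("lesion-%03d", cohort$lesion_id[i])
    ser <- tryCatch(read_series(in_dir, prefix), error = function(e)
      stop(sprintf("lesion %d: %s", cohort$lesion_id[i],
                   conditionMessage(e)), call. = FALSE))
    conds <- condition_labels(ser$ti_ms, !is.null(ser$vibe))
    recs[[i]] <- lesion_contrast_records(ser, cohort[i, , drop = FALSE])
    rois <- place_rois(ser$label_map)
    si_les <- vapply(seq_along(ser$ti_ms),
                     function(k) measure_si(ser$images[, , k], rois$lesion),
                     numeric(1))
    si_liv <- vapply(seq_along(ser$ti_ms),
                     function(k) measure_si(ser$images[, , k],
                                            rois$parenchyma), numeric(1))
    fl <- ir_fit(ser$ti_ms, si_les); fv <- ir_fit(ser$ti_ms, si_liv)
    if (fl$converged) t1_les[i] <- fl$t1_ms
    if (fv$converged) t1_liv[i] <- fv$t1_ms
  }
  tab <- do.call(rbind, recs)
  rownames(tab) <- NULL
  tab <- structure(tab, conditions = conds,
                   class = c("cohort_table", "data.frame"))
  cohort$t1_lesion_fit_ms <- t1_les
  cohort$t1_liver_fit_ms <- t1_liv

  study <- structure(list(cohort = cohort, table = tab, config = NULL,
                          acq = NULL, seed = NA_integer_, series = NULL),
                     class = "cohort_study")
  battery <- run_paper_battery(study)

  write.csv(tab, file.path(out_dir, "contrast_table.csv"),
            row.names = FALSE)
  t1sum <- data.frame(
    compartment = c("lesion", "parenchyma"),
    mean_t1_ms = c(mean(t1_les, na.rm = TRUE), mean(t1_liv, na.rm = TRUE)),
    sd_t1_ms = c(sd(t1_les, na.rm = TRUE), sd(t1_liv, na.rm = TRUE)),
    n = c(sum(!is.na(t1_les)), sum(!is.na(t1_liv))))
  write.csv(t1sum, file.path(out_dir, "t1_summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(llc_summary = battery$llc_summary, reports = battery$reports,
         alpha = battery$alpha),
    file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  con <- file(file.path(out_dir, "report.txt"), "w")
  sink(con); print(battery); sink()
  close(con)
  invisible(list(table = tab, cohort = cohort, battery = battery))
}
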