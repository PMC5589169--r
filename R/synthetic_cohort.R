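#' Patient group labels
#'
#' `G0` = healthy controls, `G1` = type 1 diabetes without complications
#' (disease duration under 15 years), `G2` = type 1 diabetes with
#' complications (duration 15 years or more).
#'
#' @format Character vector of the three closed-set labels.
#' @export
GROUP_LEVELS <- c("G0", "G1", "G2")

#' Clinical covariate distribution parameters
#'
#' Per-group Gaussian settings for the simulated covariates. Defaults
#' emulate a matched-metabolic-control design: HbA1c separates controls
#' from diabetics but overlaps heavily between G1 and G2; cholesterol and
#' LDL means are non-decreasing with disease stage; disease duration
#' respects the under-15 / 15-plus year split; diabetics receive MDI
#' (multiple daily injections) or CSII (insulin pump) therapy with
#' per-therapy insulin-dose distributions. CSII therapy can shift the
#' membrane baseline GP (`therapy_gp_offset`), the simulator's handle on
#' the observed higher fluidity under pump therapy.
#'
#' @param hba1c_mean,hba1c_sd Named per-group mean/SD of HbA1c (%).
#' @param cholesterol_mean,cholesterol_sd Total cholesterol (mg/dl).
#' @param ldl_mean,ldl_sd LDL (mg/dl).
#' @param duration_mean,duration_sd,duration_range Disease duration
#'   (years); Gaussians truncated to the per-group ranges (G0 fixed at 0).
#' @param csii_prob Probability a diabetic patient is on CSII (vs MDI).
#' @param insulin_mean,insulin_sd Named per-therapy insulin dose (U/kg),
#'   truncated below at 0.05.
#' @param therapy_gp_offset Named additive baseline-GP offset per therapy.
#' @param patient_gp_sd SD of the patient-level random baseline-GP offset.
#' @return A `covariate_params` list.
#' @export
covariate_params <- function(
    hba1c_mean = c(G0 = 5.2, G1 = 7.9, G2 = 8.1),
    hba1c_sd = c(G0 = 0.3, G1 = 0.9, G2 = 0.9),
    cholesterol_mean = c(G0 = 170, G1 = 185, G2 = 205),
    cholesterol_sd = c(G0 = 20, G1 = 25, G2 = 30),
    ldl_mean = c(G0 = 100, G1 = 112, G2 = 128),
    ldl_sd = c(G0 = 15, G1 = 20, G2 = 25),
    duration_mean = c(G1 = 8, G2 = 22),
    duration_sd = c(G1 = 4, G2 = 5),
    duration_range = list(G1 = c(0.5, 14.9), G2 = c(15, 40)),
    csii_prob = 0.5,
    insulin_mean = c(MDI = 0.55, CSII = 0.45),
    insulin_sd = c(MDI = 0.12, CSII = 0.10),
    therapy_gp_offset = c(MDI = 0, CSII = -0.03),
    patient_gp_sd = 0.01) {
  stopifnot(
    all(GROUP_LEVELS %in% names(hba1c_mean)),
    is.unsorted(cholesterol_mean[GROUP_LEVELS]) == FALSE,
    is.unsorted(ldl_mean[GROUP_LEVELS]) == FALSE,
    csii_prob >= 0, csii_prob <= 1,
    duration_range$G1[2] < 15, duration_range$G2[1] >= 15,
    patient_gp_sd >= 0
  )
  structure(list(
    hba1c_mean = hba1c_mean, hba1c_sd = hba1c_sd,
    cholesterol_mean = cholesterol_mean, cholesterol_sd = cholesterol_sd,
    ldl_mean = ldl_mean, ldl_sd = ldl_sd,
    duration_mean = duration_mean, duration_sd = duration_sd,
    duration_range = duration_range,
    csii_prob = csii_prob,
    insulin_mean = insulin_mean, insulin_sd = insulin_sd,
    therapy_gp_offset = therapy_gp_offset,
    patient_gp_sd = patient_gp_sd
  ), class = "covariate_params")
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Draw the clinical covariates for one patient
#'
#' @param group Group label.
#' @param cp A [covariate_params()] object.
#' @param seed Optional integer seed, restored on exit.
#' @return Named list of covariate fields (`hba1c_pct`,
#'   `cholesterol_mg_dl`, `ldl_mg_dl`, `duration_years`, `therapy`,
#'   `insulin_u_per_kg`, `gp_shift`). Controls have therapy `"none"`,
#'   insulin 0 and duration 0 by construction.
#' @export
simulate_covariates <- function(group, cp = covariate_params(), seed = NULL) {
  group <- match.arg(group, GROUP_LEVELS)
  stopifnot(inherits(cp, "covariate_params"))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  hba1c <- rnorm_trunc(1, cp$hba1c_mean[[group]], cp$hba1c_sd[[group]],
                       1, 20)
  chol <- rnorm_trunc(1, cp$cholesterol_mean[[group]],
                      cp$cholesterol_sd[[group]], 50, 500)
  ldl <- rnorm_trunc(1, cp$ldl_mean[[group]], cp$ldl_sd[[group]], 20, 400)
  if (group == "G0") {
    therapy <- "none"
    insulin <- 0
    duration <- 0
  } else {
    rng <- cp$duration_range[[group]]
    duration <- rnorm_trunc(1, cp$duration_mean[[group]],
                            cp$duration_sd[[group]], rng[1], rng[2])
    therapy <- if (runif(1) < cp$csii_prob) "CSII" else "MDI"
    insulin <- rnorm_trunc(1, cp$insulin_mean[[therapy]],
                           cp$insulin_sd[[therapy]], 0.05, 3)
  }
  gp_shift <- rnorm(1, 0, cp$patient_gp_sd) +
    if (therapy == "none") 0 else cp$therapy_gp_offset[[therapy]]
  list(
    hba1c_pct = hba1c,
    cholesterol_mg_dl = chol,
    ldl_mg_dl = ldl,
    duration_years = duration,
    therapy = therapy,
    insulin_u_per_kg = insulin,
    gp_shift = gp_shift
  )
}

#' Cohort simulation configuration
#'
#' Fully determines a synthetic cohort given its seed. The default sizes
#' mirror the case-control design the package targets: 8 controls, 11
#' uncomplicated and 7 complicated diabetic patients (26 subjects, 18
#' diabetic), each imaged at 10 independent z positions.
#'
#' @param n_per_group Integer triple (G0, G1, G2) of patient counts.
#' @param images_per_patient Two-channel image pairs per patient.
#' @param image_size_px Square frame side in pixels.
#' @param pixel_size_nm Pixel pitch (default 200).
#' @param field_params A [membrane_field_params()] object.
#' @param covariate_params A [covariate_params()] object (default: the
#'   standard settings).
#' @param seed Integer master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = c(8L, 11L, 7L),
                          images_per_patient = 10L,
                          image_size_px = 256L,
                          pixel_size_nm = 200,
                          field_params = membrane_field_params(),
                          covariate_params = NULL,
                          seed = 1L) {
  if (is.null(covariate_params)) covariate_params <- covariate_params()
  stopifnot(length(n_per_group) == 3L, all(n_per_group >= 0),
            images_per_patient >= 1, image_size_px >= 8,
            inherits(field_params, "membrane_field_params"),
            inherits(covariate_params, "covariate_params"))
  structure(list(
    n_per_group = as.integer(n_per_group),
    images_per_patient = as.integer(images_per_patient),
    image_size_px = as.integer(image_size_px),
    pixel_size_nm = pixel_size_nm,
    field_params = field_params,
    covariate_params = covariate_params,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# per-patient sub-seed derived from the master seed; kept below 2^31
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + index * 16807) %% 2147483647)
}

#' Simulate a full synthetic cohort
#'
#' Deterministic given the config (including its seed): draws covariates
#' and an image stack for every patient, retaining the complete ground
#' truth (true GP fields' statistics and cluster geometry per image).
#'
#' @param config A [cohort_config()] object.
#' @return An `rbc_cohort`: list with `patients` (each a `patient_record`
#'   carrying id, group, covariates and a `stack` of
#'   `list(blue, green, field)` entries), `config`, and `ground_truth`
#'   (data.frame, one row per image with true mean/variance GP and cluster
#'   count).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- rep(GROUP_LEVELS, times = config$n_per_group)
  patients <- vector("list", length(groups))
  gt <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    pseed <- derive_seed(config$seed, i)
    set.seed(pseed)
    group <- groups[i]
    id <- sprintf("P%02d_%s", i, group)
    cov <- simulate_covariates(group, config$covariate_params)
    stack <- vector("list", config$images_per_patient)
    rows <- vector("list", config$images_per_patient)
    for (z in seq_len(config$images_per_patient)) {
      field <- simulate_gp_field(group, config$field_params,
                                 image_size_px = config$image_size_px,
                                 pixel_size_nm = config$pixel_size_nm,
                                 base_gp_shift = cov$gp_shift)
      pair <- render_channels(field, config$field_params, noise = TRUE)
      stack[[z]] <- list(blue = pair$blue, green = pair$green, field = field)
      rows[[z]] <- data.frame(
        patient = id, group = group, z = z,
        true_mean_gp = field$true_mean_gp,
        true_var_gp = field$true_var_gp,
        n_clusters = nrow(field$clusters),
        stringsAsFactors = FALSE
      )
    }
    patients[[i]] <- structure(
      c(list(id = id, group = group), cov, list(stack = stack)),
      class = "patient_record"
    )
    gt[[i]] <- do.call(rbind, rows)
  }
  structure(list(
    patients = patients,
    config = config,
    ground_truth = if (length(gt)) do.call(rbind, gt) else
      data.frame(patient = character(0))
  ), class = "rbc_cohort")
}

#' @export
print.rbc_cohort <- function(x, ...) {
  tab <- table(factor(vapply(x$patients, `[[`, "", "group"),
                      levels = GROUP_LEVELS))
  cat(sprintf("<rbc_cohort> %d patients (%s), %d image pairs each, %d px\n",
              length(x$patients),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$config$images_per_patient, x$config$image_size_px))
  invisible(x)
}

#' Cohort covariate table
#'
#' @param cohort An `rbc_cohort`.
#' @return One row per patient with id, group and all clinical covariates.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "rbc_cohort"))
  do.call(rbind, lapply(cohort$patients, function(p) data.frame(
    patient = p$id, group = p$group, hba1c_pct = p$hba1c_pct,
    cholesterol_mg_dl = p$cholesterol_mg_dl, ldl_mg_dl = p$ldl_mg_dl,
    insulin_u_per_kg = p$insulin_u_per_kg, therapy = p$therapy,
    duration_years = p$duration_years, stringsAsFactors = FALSE
  )))
}

#' Write a cohort to a directory
#'
#' Layout: `cohort.csv` (one row per patient), per-channel 16-bit TIFFs at
#' `{patient}/{z}_{band}.tif`, the ground-truth ledger as
#' `ground_truth.json`, and the generating config as `config.yaml`.
#'
#' @param cohort An `rbc_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rbc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort_table(cohort), file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  for (p in cohort$patients) {
    pdir <- file.path(dir, p$id)
    dir.create(pdir, showWarnings = FALSE)
    for (z in seq_along(p$stack)) {
      write_channel_tiff(p$stack[[z]]$blue,
                         file.path(pdir, sprintf("%03d_blue_400_460.tif", z)))
      write_channel_tiff(p$stack[[z]]$green,
                         file.path(pdir, sprintf("%03d_green_470_530.tif", z)))
    }
  }
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"), digits = NA)
  yaml::write_yaml(config_to_list(cohort$config),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort_dir()]
#'
#' Reconstructs patient records with their image stacks from
#' `cohort.csv` and the per-patient TIFFs (ground-truth fields are not
#' rehydrated; the ledger stays on disk).
#'
#' @param dir Cohort directory.
#' @param pixel_size_nm Pixel pitch of the stored images.
#' @return An `rbc_cohort` (with `config = NULL` unless `config.yaml` is
#'   present).
#' @export
read_cohort_dir <- function(dir, pixel_size_nm = 200) {
  csv <- file.path(dir, "cohort.csv")
  if (!file.exists(csv)) stop("not a cohort directory: ", dir, call. = FALSE)
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) config_from_list(yaml::read_yaml(cfg_path))
         else NULL
  if (!is.null(cfg)) pixel_size_nm <- cfg$pixel_size_nm
  patients <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$patient[i]
    pdir <- file.path(dir, id)
    blues <- sort(list.files(pdir, pattern = "_blue_400_460\\.tif$"))
    stack <- lapply(blues, function(bf) {
      gf <- sub("blue_400_460", "green_470_530", bf)
      if (!file.exists(file.path(pdir, gf)))
        stop("missing green channel for ", file.path(pdir, bf),
             call. = FALSE)
      list(
        blue = read_channel_tiff(file.path(pdir, bf), "blue_400_460",
                                 pixel_size_nm),
        green = read_channel_tiff(file.path(pdir, gf), "green_470_530",
                                  pixel_size_nm)
      )
    })
    structure(c(as.list(tab[i, , drop = FALSE])[-1],
                list(id = id, stack = stack)),
              class = "patient_record")
  })
  structure(list(patients = patients, config = cfg,
                 ground_truth = NULL), class = "rbc_cohort")
}
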