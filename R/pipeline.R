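#' Run configuration serialization
#'
#' A run is fully described by its config (cohort settings, descriptor
#' settings, classifier settings, seed); the output directory always
#' contains the exact config that produced it, so any results directory
#' can be regenerated from `config.yaml` alone.
#'
#' @name run_config
NULL

config_to_list <- function(config) {
  # yaml drops names from atomic vectors; store named vectors as maps
  yamlify <- function(lst) {
    lapply(lst, function(x) {
      if (is.atomic(x) && !is.null(names(x))) as.list(x)
      else if (is.list(x)) lapply(x, function(e) e)
      else x
    })
  }
  list(
    n_per_group = config$n_per_group,
    images_per_patient = config$images_per_patient,
    image_size_px = config$image_size_px,
    pixel_size_nm = config$pixel_size_nm,
    field_params = yamlify(unclass(config$field_params)),
    covariate_params = yamlify(unclass(config$covariate_params)),
    seed = config$seed
  )
}

config_from_list <- function(lst) {
  fp <- do.call(membrane_field_params, relist_named(lst$field_params))
  cp <- do.call(covariate_params, relist_named(lst$covariate_params))
  cohort_config(
    n_per_group = unlist(lst$n_per_group),
    images_per_patient = lst$images_per_patient,
    image_size_px = lst$image_size_px,
    pixel_size_nm = lst$pixel_size_nm,
    field_params = fp, covariate_params = cp,
    seed = lst$seed
  )
}

# yaml flattens named numeric vectors to lists; restore them
relist_named <- function(lst) {
  lapply(lst, function(x) {
    if (is.list(x) && length(x) && all(vapply(x, is.numeric, TRUE)) &&
        !is.null(names(x)) && all(lengths(x) == 1L))
      unlist(x)
    else if (is.list(x) && !is.null(names(x)) &&
             all(vapply(x, function(e) is.numeric(unlist(e)), TRUE)))
      lapply(x, unlist)
    else x
  })
}

#' Read / write a cohort config as YAML
#'
#' @param config A [cohort_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `cohort_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  config_from_list(yaml::read_yaml(path))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config_to_list(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Simulate a cohort and write it to disk
#'
#' The simulation stage of the pipeline: generates the synthetic cohort
#' the config describes and writes the standard directory layout
#' (`cohort.csv`, per-channel TIFFs, `ground_truth.json`,
#' `config.yaml`).
#'
#' @param config A [cohort_config()], or a path to a config YAML.
#' @param out_dir Output cohort directory.
#' @return The cohort directory path, invisibly; the in-memory cohort is
#'   attached as attribute `"cohort"`.
#' @export
run_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "cohort_config"))
  cohort <- simulate_cohort(config)
  write_cohort_dir(cohort, out_dir)
  out <- out_dir
  attr(out, "cohort") <- cohort
  invisible(out)
}

#' Analyze a cohort end to end
#'
#' Runs the full analysis chain on a cohort (in memory or a directory
#' from [run_simulate()] / user-supplied TIFFs plus `cohort.csv`): GP
#' maps per image (written as float TIFF + color PNG), per-channel
#' texture features, DSS leave-one-person-out evaluation, the mean-GP
#' and HbA1c Bayes baselines, and the descriptive cohort statistics.
#' Malformed images are skipped with a logged reason; more than 20%
#' skips aborts the run. Every artifact is stamped with the seed and the
#' config hash.
#'
#' @param cohort An `rbc_cohort` or a cohort directory path.
#' @param out_dir Results directory (created; the function writes only
#'   inside it).
#' @param dss_config Classifier settings ([dss_config()]; default: the
#'   standard settings).
#' @param g G-factor for GP computation.
#' @param mask_mode Feature extraction mode, `"full"` or `"cell"`.
#' @param min_area_px Debris filter for segmentation.
#' @param write_images Write per-image GP TIFF/PNG artifacts (default
#'   `TRUE`; disable for large batch runs where only the tables matter).
#' @param verbose Print per-stage progress.
#' @return Invisibly, a list with `metrics` (DSS, GP and HbA1c
#'   `metrics_report`s), `stats` (the cohort statistics report),
#'   `features`, `gp_table` (per-patient mean GP), and the paths
#'   written.
#' @export
run_analyze <- function(cohort, out_dir, dss_config = NULL,
                        g = 1, mask_mode = "full", min_area_px = 100L,
                        write_images = TRUE, verbose = FALSE) {
  if (is.null(dss_config)) dss_config <- dss_config()
  if (is.character(cohort)) cohort <- read_cohort_dir(cohort)
  stopifnot(inherits(cohort, "rbc_cohort"))
  if (length(cohort$patients) < 2L)
    stop("LOPO evaluation needs at least 2 patients", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  # --- stage 1: GP maps + per-patient mean GP ---
  say("stage gp: mapping %d patients", length(cohort$patients))
  n_img <- 0L
  skipped <- list()
  gp_rows <- list()
  for (p in cohort$patients) {
    pdir <- file.path(out_dir, "gp", p$id)
    if (write_images) dir.create(pdir, recursive = TRUE,
                                 showWarnings = FALSE)
    means <- c()
    for (z in seq_along(p$stack)) {
      n_img <- n_img + 1L
      res <- tryCatch({
        zimg <- p$stack[[z]]
        bb <- subtract_background(zimg$blue, estimate_background(zimg$blue))
        gg <- subtract_background(zimg$green,
                                  estimate_background(zimg$green))
        mask <- segment_cells(bb, gg, min_area_px)
        if (!any(mask)) stop("no cells after segmentation")
        gp <- compute_gp_map(bb, gg, g = g, mask = mask)
        if (write_images)
          write_gp_map(gp,
                       tiff_path = file.path(pdir, sprintf("%03d_gp.tif", z)),
                       png_path = file.path(pdir, sprintf("%03d_gp.png", z)))
        gp_summary(gp)$mean_gp
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1L]] <-
          sprintf("%s z=%d: %s", p$id, z, conditionMessage(res))
      } else {
        means <- c(means, res)
      }
    }
    if (length(means) == 0L)
      stop("every image of patient ", p$id, " was skipped", call. = FALSE)
    gp_rows[[p$id]] <- data.frame(patient = p$id, group = p$group,
                                  mean_gp = mean(means),
                                  n_images = length(means),
                                  stringsAsFactors = FALSE)
  }
  if (length(skipped) / n_img > 0.2)
    stop(sprintf("%d of %d images skipped (> 20%%); aborting:\n%s",
                 length(skipped), n_img,
                 paste(skipped, collapse = "\n")), call. = FALSE)
  gp_table <- do.call(rbind, gp_rows)

  # --- stage 2: features ---
  say("stage features: extracting descriptors")
  features <- extract_cohort_features(cohort, mask_mode = mask_mode,
                                      min_area_px = min_area_px)
  write_feature_csv(features, file.path(out_dir, "features.csv"))

  # --- stage 3: DSS LOPO + baselines ---
  say("stage classify: LOPO over %d patients", length(cohort$patients))
  dss_report <- lopo_evaluate(features$patients, dss_config)
  tab <- cohort_table_or_stored(cohort)
  tab <- tab[match(gp_table$patient, tab$patient), ]
  gp_report <- lopo_bayes_scalar(gp_table$mean_gp, tab$group,
                                 ids = tab$patient)
  hba1c_report <- lopo_bayes_scalar(tab$hba1c_pct, tab$group,
                                    ids = tab$patient)

  # --- stage 4: cohort statistics ---
  say("stage stats: descriptive report")
  stats_report <- cohort_statistics_report(tab, gp_table$mean_gp)

  seed <- if (!is.null(cohort$config)) cohort$config$seed else NA
  stamp <- list(
    seed = seed,
    config_md5 = if (!is.null(cohort$config)) config_hash(cohort$config)
                 else NA,
    skipped_images = unlist(skipped)
  )
  utils::write.csv(dss_report$predictions,
                   file.path(out_dir, "predictions.csv"), row.names = FALSE)
  utils::write.csv(gp_table, file.path(out_dir, "gp_means.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(meta = stamp,
         dss = metrics_to_list(dss_report),
         gp_baseline = metrics_to_list(gp_report),
         hba1c_baseline = metrics_to_list(hba1c_report)),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(meta = stamp,
                            stats = serialize_stats(stats_report)),
                       file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(cohort$config))
    write_run_config(cohort$config, file.path(out_dir, "config.yaml"))

  invisible(list(
    metrics = list(dss = dss_report, gp_baseline = gp_report,
                   hba1c_baseline = hba1c_report),
    stats = stats_report,
    features = features,
    gp_table = gp_table,
    out_dir = out_dir
  ))
}

cohort_table_or_stored <- function(cohort) {
  if (!is.null(cohort$patients[[1]]$hba1c_pct)) return(cohort_table(cohort))
  stop("cohort carries no covariates", call. = FALSE)
}

metrics_to_list <- function(rep) {
  list(confusion = unclass(rep$confusion), accuracy = rep$accuracy,
       precision = as.list(rep$precision), recall = as.list(rep$recall),
       f1 = as.list(rep$f1), n = rep$n)
}

serialize_stats <- function(st) {
  clean <- function(x) {
    if (inherits(x, "group_comparison")) return(unclass(x))
    if (is.list(x)) return(lapply(x, clean))
    x
  }
  clean(st)
}

#' Write simple publication-style figures for a cohort
#'
#' Base-graphics PNG panels: mean GP by group, normalized GP and HbA1c
#' against disease duration, and the (insulin dose, GP) therapy plane.
#'
#' @param tab Cohort covariate table.
#' @param gp_mean Per-patient mean GP aligned with `tab`.
#' @param out_dir Directory for the PNGs.
#' @return Invisibly, the written paths.
#' @export
write_stats_figures <- function(tab, gp_mean, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  f1 <- file.path(out_dir, "gp_by_group.png")
  grDevices::png(f1, width = 600, height = 450)
  boxplot(gp_mean ~ factor(tab$group, levels = GROUP_LEVELS),
          xlab = "group", ylab = "mean GP", col = "grey85")
  grDevices::dev.off()
  paths <- c(paths, f1)
  dia <- tab$group != "G0"
  if (any(dia) && any(!dia)) {
    f2 <- file.path(out_dir, "normalized_vs_duration.png")
    gp_n <- gp_mean / mean(gp_mean[!dia])
    hb_n <- tab$hba1c_pct / mean(tab$hba1c_pct[!dia])
    grDevices::png(f2, width = 600, height = 450)
    plot(tab$duration_years[dia], gp_n[dia], pch = 19, col = "steelblue",
         xlab = "years since diagnosis", ylab = "value / control mean",
         ylim = range(c(gp_n[dia], hb_n[dia])))
    points(tab$duration_years[dia], hb_n[dia], pch = 17, col = "tomato")
    legend("topleft", legend = c("GP / GP0", "HbA1c / HbA1c0"),
           pch = c(19, 17), col = c("steelblue", "tomato"), bty = "n")
    grDevices::dev.off()
    paths <- c(paths, f2)
  }
  if (any(tab$therapy %in% c("MDI", "CSII"))) {
    f3 <- file.path(out_dir, "therapy_plane.png")
    sel <- tab$therapy %in% c("MDI", "CSII")
    grDevices::png(f3, width = 600, height = 450)
    plot(tab$insulin_u_per_kg[sel], gp_mean[sel],
         pch = ifelse(tab$therapy[sel] == "MDI", 19, 17),
         col = ifelse(tab$therapy[sel] == "MDI", "tomato", "steelblue"),
         xlab = "insulin (U/kg)", ylab = "mean GP")
    legend("topright", legend = c("MDI", "CSII"), pch = c(19, 17),
           col = c("tomato", "steelblue"), bty = "n")
    grDevices::dev.off()
    paths <- c(paths, f3)
  }
  invisible(paths)
}
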