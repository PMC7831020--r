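#' Pipeline run configuration
#'
#' Validated bundle of everything one end-to-end run needs: the synthetic
#' cohort and toy-atlas parameters (or paths to existing data — see
#' [read_mask()]/[read_atlas()] for assembling such cohorts manually),
#' analysis parameters and the output directory. All randomness flows from
#' the single `seed`.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed recorded in the manifest.
#' @param n_patients synthetic cohort size.
#' @param shape toy atlas grid shape.
#' @param n_lateral_pairs,n_midline,infratentorial_fraction toy atlas layout.
#' @param voxel_volume voxel volume in mm^3.
#' @param connectivity lesion/cluster labeling connectivity (6/18/26).
#' @param alpha ADIFFI per-voxel significance threshold, in (0, 1).
#' @param min_cluster_size minimum significant-cluster size in voxels.
#' @param fdr apply Benjamini-Hochberg across voxels in ADIFFI.
#' @param adiffi_covariate records column whose two most frequent values
#'   define the ADIFFI phenotypes (default "sex").
#' @param medians named list of fixed stratification medians, or empty for
#'   from-data medians.
#' @param cohort extra arguments passed to [cohort_spec()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, n_patients = 60,
                       shape = c(24, 24, 24), n_lateral_pairs = 8,
                       n_midline = 2, infratentorial_fraction = 0.25,
                       voxel_volume = 0.08, connectivity = 26,
                       alpha = 0.05, min_cluster_size = 1, fdr = FALSE,
                       adiffi_covariate = "sex", medians = list(),
                       cohort = list()) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  if (min_cluster_size < 1) stop("min_cluster_size must be >= 1")
  if (n_patients < 2) stop("n_patients must be >= 2")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_patients = as.integer(n_patients),
                 shape = as.integer(shape),
                 n_lateral_pairs = as.integer(n_lateral_pairs),
                 n_midline = as.integer(n_midline),
                 infratentorial_fraction = infratentorial_fraction,
                 voxel_volume = voxel_volume,
                 connectivity = as.integer(connectivity),
                 alpha = alpha, min_cluster_size = as.integer(min_cluster_size),
                 fdr = isTRUE(fdr), adiffi_covariate = adiffi_covariate,
                 medians = medians, cohort = cohort),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys are [run_config()] arguments; a `cohort` mapping is passed
#' through to [cohort_spec()].
#'
#' @param path YAML file; must contain `out_dir` (or it is supplied here).
#' @param out_dir optional override of the output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate, metrics, freqmap, adiffi, rmr,
#' survival, summary — writing each stage's outputs under the configured
#' directory, and returns (and writes) a run manifest with the parameter
#' echo, per-file MD5 hashes and the stage list. Deterministic under a fixed
#' seed: a rerun with the same config yields byte-identical tables.
#'
#' @param config [run_config()].
#' @param stages subset of stages to write outputs for (simulation always
#'   runs in-memory as the data source).
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "metrics", "freqmap",
                                    "adiffi", "rmr", "survival", "summary"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "metrics", "freqmap", "adiffi", "rmr",
                  "survival", "summary")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  outputs <- character()
  done <- character()
  run_stage <- function(name, fun) {
    say("[bmmap] stage: ", name)
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    done <<- c(done, name)
  }
  write_table <- function(df, file) {
    path <- file.path(config$out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  atlas <- NULL; cohort <- NULL
  run_stage("simulate", function() {
    atlas <<- build_toy_atlas(config$shape, config$n_lateral_pairs,
                              config$n_midline,
                              config$infratentorial_fraction,
                              config$voxel_volume)
    spec <- do.call(cohort_spec,
                    c(list(n_patients = config$n_patients,
                           seed = config$seed), config$cohort))
    cohort <<- simulate_cohort(spec, atlas, config$connectivity)
    if ("simulate" %in% stages) {
      write_atlas(atlas, file.path(config$out_dir, "atlas.nii"),
                  file.path(config$out_dir, "atlas_regions.tsv"))
      outputs <<- c(outputs, file.path(config$out_dir, "atlas.nii"),
                    file.path(config$out_dir, "atlas_regions.tsv"))
      mask_dir <- file.path(config$out_dir, "masks")
      dir.create(mask_dir, showWarnings = FALSE)
      for (m in cohort$masks) {
        p <- file.path(mask_dir, paste0(m$patient_id, ".nii"))
        write_map(m$data, m$grid, p, datatype = "uint8")
        outputs <<- c(outputs, p)
      }
      write_table(cohort$records, "covariates.csv")
    }
  })

  if ("metrics" %in% stages) run_stage("metrics", function() {
    write_table(cohort$lesions, "lesions.csv")
    write_table(cohort$summaries, "patient_summaries.csv")
    write_table(region_summary(cohort$lesions, atlas), "region_summary.csv")
  })

  if ("freqmap" %in% stages) run_stage("freqmap", function() {
    fm <- frequency_map(cohort$masks)
    p <- file.path(config$out_dir, "frequency_map.nii")
    write_map(fm$counts, fm$grid, p)
    outputs <<- c(outputs, p)
  })

  if ("adiffi" %in% stages) run_stage("adiffi", function() {
    cov <- cohort$records[[config$adiffi_covariate]]
    if (is.null(cov)) stop("unknown ADIFFI covariate: ",
                           config$adiffi_covariate)
    tab <- sort(table(cov), decreasing = TRUE)
    if (length(tab) < 2L) stop("ADIFFI covariate has fewer than two values")
    lv <- names(tab)[1:2]
    pm <- adiffi_map(cohort$masks[which(cov == lv[1])],
                     cohort$masks[which(cov == lv[2])], fdr = config$fdr)
    p1 <- file.path(config$out_dir, "adiffi_p.nii")
    p2 <- file.path(config$out_dir, "adiffi_direction.nii")
    write_map(pm$p, pm$grid, p1)
    write_map(pm$direction, pm$grid, p2, datatype = "int16")
    outputs <<- c(outputs, p1, p2)
    cl <- extract_clusters(pm, config$alpha, config$min_cluster_size,
                           atlas, config$connectivity,
                           use_fdr = config$fdr)
    cl$phenotype_A <- if (nrow(cl)) lv[1] else character(0)
    cl$phenotype_B <- if (nrow(cl)) lv[2] else character(0)
    write_table(cl, "adiffi_clusters.csv")
  })

  if ("rmr" %in% stages) run_stage("rmr", function() {
    write_table(relative_metastatic_risk(cohort$lesions, atlas,
                                         config$n_patients), "rmr.csv")
  })

  strata <- NULL
  if ("survival" %in% stages) run_stage("survival", function() {
    strata <<- build_strata(cohort$records, cohort$summaries,
                            medians = config$medians)
    km_rows <- list()
    for (f in c("age_group", "sex", "number_group", "infratentorial")) {
      for (lv in levels(strata[[f]])) {
        sel <- !is.na(strata[[f]]) & strata[[f]] == lv
        if (!any(sel)) next
        km <- km_estimate(strata$os_time[sel], strata$event[sel])
        km_rows[[length(km_rows) + 1L]] <- data.frame(
          factor = f, level = lv, n = km$n, events = km$n_events,
          median_os = km$median)
      }
      sel <- !is.na(strata[[f]])
      lr <- logrank_test(strata$os_time[sel], strata$event[sel],
                         strata[[f]][sel])
      km_rows[[length(km_rows) + 1L]] <- data.frame(
        factor = f, level = "(log-rank)", n = sum(sel), events = NA,
        median_os = lr$p.value)
    }
    write_table(do.call(rbind, km_rows), "km_logrank.csv")
    cox_factors <- c("age_group", "sex", "primary_group", "number_group",
                     "tv_group", "infratentorial")
    cox_factors <- Filter(function(f)
      length(unique(stats::na.omit(strata[[f]]))) >= 2L, cox_factors)
    cox <- rbind(cox_regression(strata, cox_factors, "univariate"),
                 cox_regression(strata, cox_factors, "multivariate"))
    write_table(cox, "cox.csv")
  })

  if ("summary" %in% stages) run_stage("summary", function() {
    write_table(demographic_summary(cohort$records, cohort$summaries),
                "demographics.csv")
  })

  manifest <- list(
    package = "bmmap",
    version = as.character(utils::packageVersion("bmmap")),
    seed = config$seed,
    parameters = config[setdiff(names(unclass(config)), "out_dir")],
    stages = done,
    outputs = lapply(sort(outputs), function(p)
      list(path = sub("^/*", "", sub(config$out_dir, "", p, fixed = TRUE)),
           md5 = unname(tools::md5sum(p)))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("[bmmap] done: ", length(outputs), " outputs, manifest at ",
      manifest_path)
  invisible(manifest)
}

# one-decimal half-up rounding used for percentage display
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Demographic summary table
#'
#' Counts and percentages by category in the customary demographics-table
#' layout. Denominators follow the reporting convention: the full cohort for
#' sex, primaries and lesion-number groups; the lung subset for lung
#' subtypes; the treated subset for treatment categories. Percentages are
#' rounded half-up to one decimal.
#'
#' @param records patient covariates (sex, primary_class, lung_subtype,
#'   treatments; optionally os_time/event).
#' @param summaries per-patient lesion summaries (number_group); optional.
#' @return data.frame: parameter, category, count, denominator, percent.
#' @export
demographic_summary <- function(records, summaries = NULL) {
  if (nrow(records) == 0L) stop("empty cohort")
  n <- nrow(records)
  rows <- list()
  add <- function(parameter, values, denominator, levels_order = NULL) {
    values <- values[!is.na(values)]
    tab <- table(values)
    if (!is.null(levels_order))
      tab <- tab[intersect(levels_order, names(tab))]
    for (nm in names(tab)) {
      cnt <- as.integer(tab[[nm]])
      rows[[length(rows) + 1L]] <<- data.frame(
        parameter = parameter, category = nm, count = cnt,
        denominator = denominator,
        percent = if (denominator > 0) round_half_up(100 * cnt / denominator)
        else 0.0,
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(records$sex)) add("sex", records$sex, n)
  if (!is.null(records$primary_class)) {
    add("primary", records$primary_class, n)
    lung <- records$primary_class == "lung"
    if (any(lung) && !is.null(records$lung_subtype))
      add("lung subtype", records$lung_subtype[lung], sum(lung))
  }
  if (!is.null(summaries) && !is.null(summaries$number_group))
    add("number of metastases", summaries$number_group, nrow(summaries),
        levels_order = c("1", "2", "3+"))
  if (!is.null(records$treatments)) {
    treated <- !is.na(records$treatments)
    if (any(treated)) add("treatment", records$treatments[treated],
                          sum(treated))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
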