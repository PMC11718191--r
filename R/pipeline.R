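## Pipeline orchestration: a single configuration object drives
## simulate -> equilibrium/treatment -> tracer analysis -> assay
## reduction -> phenotyping, with a manifest for reproducibility.

# Pinned defaults for every constant the analysis chooses where the
# protocol leaves a gap; visible and overridable in one place.
default_constants <- function() {
  list(cbg_kd_nM = 10, albumin_n_ratio = 1.74, affinity_ratio = 10,
       units_to_umolar = 1, si = 1, k_cleave = log(10) / 40,
       cv_threshold_pct = 5, steady_window_min = c(180, 270),
       insulin_pmolL_per_mUL = 6.945)
}

known_config_keys <- c("stages", "out_dir", "seed", "constants",
                       "n_replicates", "n_per_group", "n_per_arm",
                       "log_level")

#' Build or load a pipeline run configuration
#'
#' A run configuration selects pipeline stages, the output directory,
#' the seed, and a constants block holding every pinned default
#' (equilibrium constants, protease constants, steadiness threshold and
#' window, unit conversions). Unknown keys are rejected. The object
#' round-trips unchanged through [write_run_config()] /
#' `run_config(path)`.
#'
#' @param config Either a named list of settings or a path to a YAML or
#'   JSON configuration file.
#' @return An object of class `gc_run_config`.
#' @export
#' @examples
#' cfg <- run_config(list(stages = "simulate", out_dir = tempfile(),
#'                        seed = 1))
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), known_config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  all_stages <- c("simulate", "equilibrium", "tracer", "assay", "phenotype")
  stages <- config$stages %||% all_stages
  stages <- unlist(stages)
  if (!all(stages %in% all_stages))
    stop("unknown stage(s): ",
         paste(setdiff(stages, all_stages), collapse = ", "), call. = FALSE)

  constants <- utils::modifyList(default_constants(),
                                 config$constants %||% list())
  structure(list(stages = stages,
                 out_dir = config$out_dir %||% file.path(tempdir(),
                                                         "gcflux_run"),
                 seed = as.integer(config$seed %||% 1L),
                 constants = constants,
                 n_replicates = config$n_replicates %||% 4L,
                 n_per_group = config$n_per_group %||% 16L,
                 n_per_arm = config$n_per_arm %||% 7L,
                 log_level = config$log_level %||% "info"),
            class = "gc_run_config")
}

#' @rdname run_config
#' @param cfg A `gc_run_config`.
#' @param path Output file path (`.yaml` or `.json`).
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "gc_run_config"))
  lst <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path, precision = 15)
  }
  invisible(path)
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message("[gcflux] ", sprintf(...))
}

#' Run the analysis pipeline
#'
#' Executes the selected stages on synthetic data: `simulate` generates
#' the serum panel, the tracer study and the mouse cohort (writing each
#' table plus its ground truth); `equilibrium` re-solves and writes the
#' reference partition; `tracer` runs [analyze_study()] on the generated
#' plasma table; `assay` closes the loop from simulated ultrafiltration
#' counts back to free fractions; `phenotype` computes HOMA-IR, GTT AUC,
#' kITT and the insulin delta per animal. A manifest (seed, constants,
#' stage list, file checksums) is written beside the outputs; identical
#' configuration and seed produce byte-identical outputs. On error,
#' partial outputs of the failed run are removed.
#'
#' @param config A `gc_run_config`, a named list, or a path to a config
#'   file (see [run_config()]).
#' @return Invisibly, a list with `status` (`"ok"`), `out_dir` and the
#'   `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "gc_run_config")) config else
    run_config(config)
  out <- cfg$out_dir
  created <- !dir.exists(out)
  if (created) dir.create(out, recursive = TRUE)
  written <- character(0)
  cst <- cfg$constants

  emit <- function(df, name) {
    p <- file.path(out, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  emit_json <- function(obj, name) {
    p <- file.path(out, name)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    written <<- c(written, p)
    p
  }

  result <- tryCatch({
    protocol <- tracer_protocol(
      steady_window_min = unlist(cst$steady_window_min),
      cv_threshold_pct = cst$cv_threshold_pct)
    panel <- NULL; tracer <- NULL; mouse <- NULL

    if ("simulate" %in% cfg$stages || "tracer" %in% cfg$stages ||
        "assay" %in% cfg$stages || "phenotype" %in% cfg$stages) {
      pipeline_log(cfg, "simulating (seed %d)", cfg$seed)
      panel <- gen_serum_panel(cfg$seed, cfg$n_replicates)
      tracer <- gen_tracer_study(cfg$seed, cfg$n_per_group, protocol)
      mouse <- gen_mouse_cohort(cfg$seed, n_per_arm = cfg$n_per_arm)
      emit(panel$panel, "serum_panel.csv")
      emit(tracer$samples, "plasma_samples.csv")
      emit(mouse$weights, "mouse_weights.csv")
      emit(mouse$gtt, "mouse_gtt.csv")
      emit(mouse$itt, "mouse_itt.csv")
      emit(mouse$insulin, "mouse_insulin.csv")
      emit(mouse$tissue, "mouse_tissue.csv")
      emit_json(list(serum_panel = panel$truth$pre_noise,
                     tracer_subjects = tracer$truth$subjects,
                     mouse_arms = mouse$truth$arms,
                     seed = cfg$seed),
                "truth.json")
    }

    if ("equilibrium" %in% cfg$stages) {
      pipeline_log(cfg, "solving reference equilibrium")
      ref <- reference_serum(cbg_kd = cst$cbg_kd_nM,
                             albumin_ratio = cst$albumin_n_ratio)
      emit(as.data.frame(solve_free(ref)), "reference_partition.csv")
    }

    if ("tracer" %in% cfg$stages) {
      pipeline_log(cfg, "analysing tracer study")
      study <- analyze_study(tracer$samples, protocol)
      emit(study$results, "tracer_results.csv")
      if (!is.null(study$balances)) emit(study$balances,
                                         "tissue_balance.csv")
      if (!is.null(study$summary)) emit(study$summary, "group_summary.csv")
    }

    if ("assay" %in% cfg$stages) {
      pipeline_log(cfg, "reducing simulated assays")
      pre <- panel$truth$pre_noise
      ff <- vapply(seq_len(nrow(pre)), function(i) {
        part <- structure(list(free = pre$free_nM[i],
                               total_steroid = pre$free_nM[i] /
                                 (pre$free_fraction_pct[i] / 100)),
                          class = "gc_partition")
        cnt <- simulate_ultrafiltration_counts(part)
        ultrafiltration_free_fraction(cnt$cpm_filtrate, cnt$cpm_retentate)
      }, 0)
      emit(data.frame(sample_id = pre$sample_id,
                      free_fraction_pct = ff,
                      truth_free_fraction_pct = pre$free_fraction_pct,
                      stringsAsFactors = FALSE),
           "ultrafiltration_free_fractions.csv")
    }

    if ("phenotype" %in% cfg$stages) {
      pipeline_log(cfg, "computing metabolic indices")
      idx <- do.call(rbind, lapply(
        unique(mouse$insulin$animal_id), function(aid) {
          ins <- mouse$insulin[mouse$insulin$animal_id == aid, ]
          g <- mouse$gtt[mouse$gtt$animal_id == aid, ]
          it <- mouse$itt[mouse$itt$animal_id == aid, ]
          data.frame(
            animal_id = aid, genotype = ins$genotype, sex = ins$sex,
            surgery = ins$surgery,
            homa_ir = homa_ir(ins$fasting_glucose_mM,
                              ins$fasting_insulin_pmolL, "pmol_L"),
            gtt_auc = gtt_auc(glucose_curve(aid, "GTT", g$time_min,
                                            g$glucose_mM)),
            kitt_pct_min = kitt(glucose_curve(aid, "ITT", it$time_min,
                                              it$glucose_mM)),
            insulin_delta_pmolL = insulin_delta(ins$fasting_insulin_pmolL,
                                                ins$insulin_15min_pmolL),
            stringsAsFactors = FALSE)
        }))
      rownames(idx) <- NULL
      emit(idx, "metabolic_indices.csv")
    }

    manifest <- list(seed = cfg$seed, stages = cfg$stages,
                     constants = cst,
                     n_replicates = cfg$n_replicates,
                     n_per_group = cfg$n_per_group,
                     n_per_arm = cfg$n_per_arm,
                     outputs = lapply(written, function(p)
                       list(file = basename(p),
                            md5 = unname(tools::md5sum(p)))))
    emit_json(manifest, "manifest.json")
    list(status = "ok", out_dir = out, manifest = manifest)
  }, error = function(e) {
    # remove partial outputs of the failed run
    unlink(written)
    if (created) unlink(out, recursive = TRUE)
    stop(e)
  })
  pipeline_log(cfg, "done: %d files in %s",
               length(result$manifest$outputs), out)
  invisible(result)
}
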