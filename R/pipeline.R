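# Run configuration and the end-to-end pipeline driver.

#' Default run configuration
#'
#' Flat key space covering every tunable of the workflow. A YAML file (or
#' named list) can override any key; unknown keys are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param overrides Named list or path to a YAML file.
#' @return Named list of resolved configuration values.
#' @export
run_config <- function(overrides = NULL) {
  defaults <- list(
    seed = 1L,
    # synthetic inputs (used when no library/PSM files are given)
    n_proteins = 25L,
    mean_protein_length = 400,
    rt_jitter_sd = 0.1,
    # gradients
    source_gradient_min = 120,
    source_gradient_label = "source",
    dest_gradient_min = 20,
    dest_gradient_label = "destination",
    # gradient transfer simulation
    transfer_slope = NA,          # NA: dest length / source length
    transfer_intercept = 0.2,
    transfer_quad = 0,
    transfer_noise_sd = 0.02,
    # file inputs (override the simulator when set)
    library_tsv = NA,
    psm_tsv = NA,
    mgf = NA,
    measured_rt_tsv = NA,
    annotation_tol_da = 0.1,
    # landmarks / calibration
    n_landmarks = 12L,
    landmark_intensity_quantile = 0.5,
    # selection rules
    min_length = 6L, max_length = 25L, max_missed_cleavages = 0L,
    allow_variable_mods = FALSE, allowed_precursor_charges = c(2L, 3L),
    require_proteotypic = TRUE, peptides_per_protein = 5L,
    fragments_per_peptide = 6L, min_fragment_index = 3L,
    series_allowed = "y",
    # scheduling
    window_width_min = 0.4,
    cycle_time_s = 1,
    max_concurrent_limit = 200L,
    interscan_overhead_ms = 0.5,
    min_dwell_ms = 5
  )
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    defaults[names(overrides)] <- overrides
  }
  defaults
}

config_rules <- function(cfg) {
  selection_rules(
    min_length = cfg$min_length, max_length = cfg$max_length,
    max_missed_cleavages = cfg$max_missed_cleavages,
    allow_variable_mods = cfg$allow_variable_mods,
    allowed_precursor_charges = cfg$allowed_precursor_charges,
    require_proteotypic = cfg$require_proteotypic,
    peptides_per_protein = cfg$peptides_per_protein,
    fragments_per_peptide = cfg$fragments_per_peptide,
    min_fragment_index = cfg$min_fragment_index,
    series_allowed = cfg$series_allowed)
}

#' Run the full shotgun-to-SRM workflow
#'
#' Executes library construction (or simulation), landmark selection, iRT
#' assignment, calibration to the destination gradient, target selection,
#' RT prediction, window assignment, schedule validation (splitting into
#' several methods when a single one is infeasible) and export. One log
#' line per stage; any stage failure aborts with the stage name and
#' removes partial outputs.
#'
#' Input resolution: `library_tsv` takes precedence; otherwise
#' `psm_tsv` + `mgf` are built into a library; otherwise a synthetic
#' proteome/library is simulated from the configured seed. Measured
#' destination-gradient RTs come from `measured_rt_tsv` when set, else
#' from a simulated gradient transfer.
#'
#' @param config From [run_config()] (list, YAML path, or `NULL` for
#'   defaults).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage log lines.
#' @return Invisible list with the schedule(s), calibration, target set
#'   and manifest path.
#' @export
run_pipeline <- function(config = NULL, out_dir = "srmkit_run", quiet = FALSE) {
  cfg <- if (is.list(config) && !is.null(config$seed) &&
             setequal(names(config), names(run_config()))) config
         else run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  note <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- function(name) {
    p <- file.path(out_dir, name)
    written <<- c(written, p)
    p
  }

  src_gradient <- gradient_profile(cfg$source_gradient_min, cfg$source_gradient_label)
  dest_gradient <- gradient_profile(cfg$dest_gradient_min, cfg$dest_gradient_label)

  sim <- NULL
  lib <- if (!is.na(cfg$library_tsv)) {
    stage("speclib.read_library_tsv",
          read_library_tsv(cfg$library_tsv, src_gradient))
  } else if (!is.na(cfg$psm_tsv) && !is.na(cfg$mgf)) {
    stage("speclib.build_library",
          build_library(cfg$psm_tsv, cfg$mgf, src_gradient, cfg$annotation_tol_da))
  } else {
    stage("synth.simulate_library", {
      proteome <- generate_proteome(cfg$n_proteins, cfg$mean_protein_length,
                                    seed = cfg$seed)
      sim <- simulate_library(proteome, src_gradient, seed = cfg$seed,
                              params = synth_params(rt_jitter_sd = cfg$rt_jitter_sd))
      sim$library
    })
  }
  note("library: ", nrow(lib$entries), " entries")

  refs <- stage("rtcal.pick_landmarks",
                pick_landmarks(lib, cfg$n_landmarks, cfg$landmark_intensity_quantile))
  note("landmarks: ", nrow(refs), " reference peptides")
  lib <- stage("rtcal.assign_irt", assign_irt(lib, refs))

  measured <- if (!is.na(cfg$measured_rt_tsv)) {
    stage("rtcal.read_measured_rt_tsv", read_measured_rt_tsv(cfg$measured_rt_tsv))
  } else {
    stage("synth.simulate_transfer", {
      slope <- if (is.na(cfg$transfer_slope))
        cfg$dest_gradient_min / cfg$source_gradient_min else cfg$transfer_slope
      model <- transfer_model(slope, cfg$transfer_intercept, cfg$transfer_quad,
                              cfg$transfer_noise_sd, seed = cfg$seed)
      simulate_transfer(lib, model, refs)$measured
    })
  }
  cal <- stage("rtcal.calibrate", calibrate(refs, measured))
  note(sprintf("calibration: slope %.5f min/iRT, r^2 %.5f, %d points",
               cal$slope, cal$r_squared, cal$n_used))

  targets <- stage("selector.select_targets",
                   select_targets(lib, config_rules(cfg)))
  note("targets: ", nrow(targets), " transitions, ",
       length(unique(targets$key)), " peptides")
  if (!nrow(targets)) stop("pipeline aborted at stage 'selector.select_targets': no targets selected")

  targets$predicted_rt <- as.numeric(predict_rt(targets$irt, cal))
  windowed <- stage("scheduler.assign_windows",
                    assign_windows(targets, cfg$window_width_min, dest_gradient))
  sched <- mrm_schedule(windowed, dest_gradient, cfg$cycle_time_s,
                        cfg$max_concurrent_limit)
  report <- validate_schedule(sched, cfg$interscan_overhead_ms, cfg$min_dwell_ms)
  schedules <- list(sched)
  if (report$status != "PASS") {
    note("single method FAILs (max concurrency ", report$max_concurrency,
         "); splitting")
    schedules <- stage("scheduler.split_methods",
                       split_methods(windowed, dest_gradient, cfg$cycle_time_s,
                                     cfg$max_concurrent_limit,
                                     cfg$interscan_overhead_ms, cfg$min_dwell_ms))
  }
  note("schedule: ", length(schedules), " method(s), max concurrency ",
       max(vapply(schedules, function(s) s$concurrency$max_concurrency, 0L)))

  stage("export", {
    write_library_tsv(lib, out("library.tsv"))
    write_targets_tsv(targets, out("targets.tsv"))
    write_calibration_report(cal, out("calibration.txt"))
    out("calibration.txt.kv")  # registered for cleanup; written above
    export_skyline_csv(targets, out("transitions_skyline.csv"))
    for (i in seq_along(schedules))
      export_dmrm_csv(schedules[[i]],
                      out(sprintf("method_%02d_dmrm.csv", i)))
  })

  cfg_path <- out("config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  manifest <- list(
    config_file = "config.yaml",
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed,
    library_entries = nrow(lib$entries),
    landmarks = nrow(refs),
    calibration = list(slope = cal$slope, intercept = cal$intercept,
                       r_squared = cal$r_squared, n_used = cal$n_used),
    transitions = nrow(targets),
    methods = length(schedules),
    max_concurrency = max(vapply(schedules, function(s)
      s$concurrency$max_concurrency, 0L)),
    validation = if (length(schedules) == 1L) report$status else "PASS",
    outputs = basename(written)
  )
  yaml::write_yaml(manifest, out("manifest.yaml"))
  note("validation: ", manifest$validation)
  invisible(list(library = lib, calibration = cal, targets = targets,
                 schedules = schedules, manifest = manifest,
                 manifest_path = file.path(out_dir, "manifest.yaml"),
                 ground_truth = if (!is.null(sim)) sim$ground_truth else NULL))
}
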