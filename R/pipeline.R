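#' Default pipeline configuration
#'
#' Builds a fully specified configuration list for [run_pipeline()].
#' Every stage parameter has the analysis default; any entry can be
#' overridden.  Configurations are plain lists and can be round-tripped
#' through YAML.
#'
#' @param out_dir Output directory.
#' @param seed Global seed; every stage derives its own sub-stream.
#' @param n_per_group Subjects per group of the simulated study.
#' @param grid_shape Voxel grid of the simulated whole-brain stage.
#' @param n_timepoints Frames per scan.
#' @param n_permutations Permutations for the cluster-extent null.
#' @param ... Further overrides (must be known fields).
#' @return Named list of class `taskconn_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("taskconn_run_"), seed = 1L,
                            n_per_group = 4, grid_shape = c(12, 12, 12),
                            n_timepoints = 60, n_permutations = 100, ...) {
  cfg <- list(
    out_dir = out_dir, seed = seed, n_per_group = n_per_group,
    grid_shape = grid_shape, n_timepoints = n_timepoints,
    n_permutations = n_permutations,
    effects = effect_spec(), mixing = 0.5,
    fd_threshold_mm = 0.3, max_censored_fraction = 0.05,
    band_low_hz = 0.01, band_high_hz = 0.1, fwhm_mm = 4,
    alpha = 0.05, p_two_tailed = 0.05, connectivity = 6,
    driver_p = 0.001, driver_extent = 20, fdr_q = 0.05)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = c("taskconn_config", "list"))
}

validate_config <- function(config) {
  required <- c("out_dir", "seed", "n_per_group", "grid_shape",
                "n_timepoints", "n_permutations", "effects")
  for (field in required) {
    if (is.null(config[[field]])) {
      abort(sprintf("config field '%s' is missing.", field))
    }
  }
  if (!inherits(config$effects, "effect_spec")) {
    config$effects <- do.call(effect_spec, as.list(config$effects))
  }
  config
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes every stage on a simulated study: design and ROI/voxel/
#' behaviour generation, motion QC, network and edge mixed-model
#' contrasts, global-connectedness maps with permutation cluster-extent
#' inference, driver classification with the allegiance chi-square, and
#' the robust brain-behaviour regression.  All stage outputs are written
#' as CSV under `config$out_dir` together with a JSON manifest (resolved
#' configuration, seeds, output checksums).  Identical configurations
#' produce byte-identical numeric outputs.
#'
#' @param config A [pipeline_config()] (or a list/YAML path coercible to
#'   one).
#' @return The manifest (a list), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found.", config))
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  outputs <- character()
  save_csv <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  design <- make_design(config$n_per_group, seed = derive_seed(seed, 1))
  save_csv(design, "design.csv")

  # motion QC
  motion <- simulate_motion(design, n_frames = config$n_timepoints,
                            seed = derive_seed(seed, 2))
  qc <- purrr::imap(motion, function(m, id) {
    mutate(qc_exclude(compute_fd(m), config$fd_threshold_mm,
                      config$max_censored_fraction), scan_id = id)
  }) |> list_rbind()
  save_csv(qc, "qc.csv")

  # ROI network stage
  atlas <- synthetic_atlas()
  roi <- simulate_roi_timeseries(design, atlas, config$effects,
                                 n_timepoints = max(config$n_timepoints, 100),
                                 seed = derive_seed(seed, 3))
  mats <- lapply(roi$series, connectivity_matrix)
  net_tab <- network_connectivity_table(mats, roi$scans, atlas)
  save_csv(net_tab, "network_connectivity.csv")
  lme_fits <- net_tab |>
    group_by(.data$network) |>
    group_modify(~glance(fit_lme(.x, model = "threeway"))) |>
    ungroup()
  save_csv(lme_fits, "network_lme.csv")
  edge_tab <- edge_connectivity_table(mats, roi$scans, atlas)
  edges <- edge_interaction_tests(edge_tab, q = config$fdr_q)
  save_csv(edges, "edge_tests.csv")

  # whole-brain connectedness stage
  vox <- simulate_voxel_dataset(design, config$grid_shape,
                                effects = config$effects,
                                n_timepoints = config$n_timepoints,
                                mixing = config$mixing,
                                seed = derive_seed(seed, 4))
  maps <- lapply(vox$series, function(vs) {
    global_connectedness(vs, vox$mask, method = "fast")
  })
  statmap <- voxelwise_lme(maps, vox$scans, vox$mask, model = "threeway")
  null <- permutation_cluster_cutoff(maps, vox$scans, vox$mask,
                                     model = "threeway",
                                     n_permutations = config$n_permutations,
                                     alpha = config$alpha,
                                     p_two_tailed = config$p_two_tailed,
                                     connectivity = config$connectivity,
                                     seed = derive_seed(seed, 5))
  clusters <- apply_cutoff(
    threshold_and_label(statmap, config$p_two_tailed, config$connectivity),
    null$cutoff)
  save_csv(clusters$clusters, "clusters.csv")
  save_csv(tibble(permutation = seq_len(null$n_permutations),
                  max_cluster_size = as.integer(null$max_sizes[, 1])),
           "permutation_null.csv")

  # allegiance of surviving clusters, against spheres at the simulated
  # community centres (the ROI atlas lives in a different space)
  allegiance <- classify_allegiance(
    clusters, community_atlas(vox$community_map,
                              vox$series[[1]]$voxel_size_mm),
    reference_networks = unclass_attr(vox$community_map),
    reference_legend = attr(vox$community_map, "networks"),
    voxel_size_mm = vox$series[[1]]$voxel_size_mm)
  save_csv(allegiance, "allegiance.csv")

  # behaviour stage: per-subject interaction effect from the largest
  # surviving cluster (whole grid if none survives)
  roi_effects <- interaction_effect_per_subject(
    filter(net_tab, .data$network == "PMN") |>
      select("subject_id", "condition", "task", "value"))
  behav <- simulate_behavior(
    design,
    setNames(roi_effects$interaction_effect,
             as.character(roi_effects$subject_id)),
    config$effects, seed = derive_seed(seed, 6))
  save_csv(behav$scores, "behavior_scores.csv")
  contrast <- behavior_contrast(behav$scores)
  save_csv(contrast, "behavior_contrast.csv")
  change <- behav$scores |>
    filter(.data$assessment %in% c("post_stim", "post_sham")) |>
    select("subject_id", "assessment", "context_recollection") |>
    pivot_wider(names_from = "assessment",
                values_from = "context_recollection") |>
    mutate(memory_change = .data$post_stim - .data$post_sham)
  reg_data <- roi_effects |>
    left_join(change, by = "subject_id") |>
    left_join(summarise(group_by(roi$scans, .data$subject_id),
                        tsnr = mean(.data$tsnr), .groups = "drop"),
              by = "subject_id") |>
    filter(!is.na(.data$memory_change))
  robust <- robust_brain_behavior(reg_data)
  save_csv(glance(robust), "robust_regression.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("taskconn")),
    seed = seed,
    config = config_for_manifest(config),
    stage_seeds = setNames(as.list(vapply(1:6, derive_seed, integer(1),
                                          seed = seed)),
                           c("design", "motion", "roi", "voxel",
                             "permutation", "behavior")),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))),
    cluster_cutoff = null$cutoff,
    n_surviving_clusters = nrow(clusters$clusters))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

unclass_attr <- function(x) {
  attr(x, "networks") <- NULL
  x
}

config_for_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$effects <- unclass(cfg$effects)
  cfg
}

#' Stimulation-protocol arithmetic
#'
#' Derived quantities of a repetitive-TMS session: total pulses
#' (`trains x rate x train duration`) and total session duration
#' (`trains x (train + inter-train interval)`).
#'
#' @param trains Number of stimulation trains.
#' @param pulse_rate_hz Pulse rate within a train (Hz).
#' @param train_s Train duration (s).
#' @param inter_train_s No-stimulation gap between trains (s).
#' @return One-row tibble: `pulses`, `duration_s`, `duration_min`.
#' @examples
#' validate_protocol(40, 20, 2, 28)  # 1600 pulses, 20 min
#' @export
validate_protocol <- function(trains, pulse_rate_hz, train_s, inter_train_s) {
  assert_scalar_number(trains, "trains", positive = TRUE)
  assert_scalar_number(pulse_rate_hz, "pulse_rate_hz", positive = TRUE)
  assert_scalar_number(train_s, "train_s", positive = TRUE)
  assert_scalar_number(inter_train_s, "inter_train_s")
  if (inter_train_s < 0) abort("`inter_train_s` must be >= 0.")
  duration <- trains * (train_s + inter_train_s)
  tibble(pulses = trains * pulse_rate_hz * train_s,
         duration_s = duration, duration_min = duration / 60)
}
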