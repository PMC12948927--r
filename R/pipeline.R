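# End-to-end orchestration: simulate (or read) -> filter -> align -> alpha
# -> null-model beta -> pattern classification -> guild profiling, as one
# reproducible, seeded run with a machine-readable report.

#' Configuration for an end-to-end pipeline run
#'
#' @param sim A [sim_config()] (or plain list of its arguments) for
#'   synthetic input; mutually exclusive with `input_dir`. The simulation
#'   seed is derived from `seed` so one root seed drives the whole run.
#' @param input_dir Directory of flat files readable by [read_dataset()].
#' @param remove_singletons Apply the per-experiment singleton filter
#'   (default TRUE).
#' @param nucleic_acid Which profile to analyse, `"cDNA"` (default) or
#'   `"DNA"`.
#' @param n_mock,n_pairs Null-model size; requires `n_pairs <= n_mock / 2`.
#' @param threshold Significance band half-width (> 0; default 1.96).
#' @param seed Root seed for every source of randomness in the run.
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       remove_singletons = TRUE, nucleic_acid = "cDNA",
                       n_mock = 10000, n_pairs = 1000, threshold = 1.96,
                       seed = 1, out_dir = NULL) {
  if (threshold <= 0) abort("threshold must be positive")
  if (n_pairs > n_mock / 2) abort("n_pairs must not exceed n_mock / 2")
  if (!nucleic_acid %in% c("cDNA", "DNA")) {
    abort("nucleic_acid must be 'cDNA' or 'DNA'")
  }
  if (!is.null(input_dir) && !is.null(sim)) sim <- NULL
  if (is.null(input_dir) && is.null(sim)) {
    abort("either sim or input_dir must be given")
  }
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    sim <- do.call(sim_config, sim)
  }
  structure(list(sim = sim, input_dir = input_dir,
                 remove_singletons = isTRUE(remove_singletons),
                 nucleic_acid = nucleic_acid,
                 n_mock = as.integer(n_mock), n_pairs = as.integer(n_pairs),
                 threshold = threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The YAML mirrors the [run_config()] arguments; a `sim:` block holds
#' [sim_config()] arguments.
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$guild_mix)) y$sim$guild_mix <- unlist(y$sim$guild_mix)
    y$sim <- do.call(sim_config, y$sim)
  }
  do.call(run_config, y)
}

#' Run the full succession-analysis pipeline
#'
#' Stages: obtain the dataset (simulate or read), select the requested
#' nucleic-acid profile, apply the singleton filter, assign Before / After
#' / Furthest categories, compute alpha-diversity trajectories, pairwise
#' between-experiment beta diversity with the mock-community null and
#' z-score normalization, convergence-pattern classification,
#' within-experiment beta diversity, the Spearman time-differential bias
#' check, guild annotation with trajectories, per-category core
#' communities, and the chord-diagram edge list. Deterministic given the
#' config seed; per-experiment and per-pair child seeds isolate stages, so
#' adding an experiment leaves existing results unchanged.
#'
#' @param config A [run_config()] (or YAML path).
#' @return A list of class `slime_report`; see the elements documented in
#'   the vignette. Has a [glance()] method.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- run_config_from_yaml(config)
  stopifnot(inherits(config, "run_config"))

  ds <- if (!is.null(config$input_dir)) {
    read_dataset(config$input_dir)
  } else {
    sim <- config$sim
    sim$seed <- child_seed(config$seed, "simulate")
    simulate_dataset(validate_sim_config(unclass(sim)))
  }

  community <- dplyr::filter(ds$community,
                             .data$nucleic_acid == config$nucleic_acid)
  if (nrow(community) == 0) {
    abort(paste0("no ", config$nucleic_acid, " samples in the input"))
  }
  audit <- tibble::tibble(stage = "input",
                          n_asvs = length(unique(community$asv_id)),
                          n_samples = length(unique(community$sample_id)))
  if (config$remove_singletons) {
    community <- remove_singletons(community)
    audit <- dplyr::bind_rows(audit, tibble::tibble(
      stage = "singleton_filter",
      n_asvs = length(unique(community$asv_id)),
      n_samples = length(unique(community$sample_id))))
  }

  assignments <- assign_timepoints_all(community, ds$designs)
  alpha <- alpha_diversity(community)
  beta <- pairwise_beta(community, assignments, n_mock = config$n_mock,
                        n_pairs = config$n_pairs, seed = config$seed,
                        threshold = config$threshold)
  patterns <- classify_patterns(beta, threshold = config$threshold)
  within <- within_experiment_beta(community, n_mock = config$n_mock,
                                   n_pairs = config$n_pairs,
                                   seed = config$seed,
                                   threshold = config$threshold)
  bias <- tryCatch(time_differential_bias_check(beta),
                   error = function(e) tibble::tibble(
                     n = sum(!is.na(beta$z)), rho = NA_real_,
                     p_value = NA_real_, biased = NA))

  annotated <- annotate_guilds(community, ds$taxonomy, ds$guilds)
  guild_traj <- guild_trajectory(annotated)
  cores <- purrr::map_dfr(intersect(c("Before", "After", "Furthest"),
                                    unique(assignments$category)),
                          function(cat) {
    scope <- unique(assignments$experiment[assignments$category == cat])
    dplyr::mutate(core_community(community, assignments, cat, scope,
                                 taxonomy = ds$taxonomy),
                  category = cat, scope = paste(sort(scope), collapse = ","))
  })
  edges <- chord_edges(annotated, ds$guilds)

  report <- structure(list(
    config = config,
    provenance = list(seed = config$seed,
                      config_hash = rlang::hash(unclass(config)),
                      package_version =
                        as.character(utils::packageVersion("slimediv"))),
    filter_audit = audit,
    assignments = assignments,
    alpha = alpha,
    beta = beta,
    patterns = patterns,
    within = within,
    bias = bias,
    guild_trajectories = guild_traj,
    core_communities = cores,
    chord_edges = edges,
    truth = ds$truth,
    community = community,
    taxonomy = ds$taxonomy), class = "slime_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Emits long-format TSVs for every result table, the chord edge list as
#' CSV, and a JSON summary with provenance. Content is deterministic (no
#' timestamps), so reruns with the same config are byte-identical.
#'
#' @param report A `slime_report`.
#' @param directory Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_tsv(x, file.path(directory, f),
                                       progress = FALSE)
  w(report$alpha, "alpha.tsv")
  w(dplyr::select(report$beta, -dplyr::any_of("null")), "beta.tsv")
  w(report$patterns, "patterns.tsv")
  w(report$within, "within_experiment.tsv")
  w(report$guild_trajectories, "guild_fractions.tsv")
  w(report$core_communities, "core_communities.tsv")
  w(report$filter_audit, "filter_audit.tsv")
  readr::write_csv(report$chord_edges, file.path(directory, "chord_edges.csv"),
                   progress = FALSE)
  summary <- list(
    schema_version = 1L,
    provenance = report$provenance,
    bias_check = as.list(report$bias),
    patterns = setNames(as.list(report$patterns$label),
                        report$patterns$pair))
  jsonlite::write_json(summary, file.path(directory, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(directory)
}

#' @export
print.slime_report <- function(x, ...) {
  cat("SLiME succession report\n")
  cat(sprintf("  %d experiments, %d pair-category beta results\n",
              length(unique(x$alpha$experiment)), nrow(x$beta)))
  cat("  patterns:\n")
  for (i in seq_len(nrow(x$patterns))) {
    cat(sprintf("    %s: %s\n", x$patterns$pair[i], x$patterns$label[i]))
  }
  invisible(x)
}

#' @export
glance.slime_report <- function(x, ...) {
  tibble::tibble(
    n_experiments = length(unique(x$alpha$experiment)),
    n_pairs = length(unique(x$beta$pair)),
    n_beta_results = nrow(x$beta),
    n_persistent = sum(x$patterns$label == "persistent_convergence"),
    n_progressive = sum(x$patterns$label == "progressive_convergence"),
    n_transient = sum(x$patterns$label == "transient_convergence"),
    n_null_like = sum(x$patterns$label == "null_like"),
    mean_observed_jaccard = mean(x$beta$observed_jaccard),
    bias_p_value = x$bias$p_value[1],
    seed = x$provenance$seed)
}
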