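# Seeded generator for multi-experiment ASV count time series with the
# statistical structure the analysis assumes: partially overlapping ASV
# pools, injection-triggered loss of fermenter ASVs, post-injection
# enrichment of sulfate reducers and methanogens, and matching taxonomy,
# guild and event-log tables.

#' Configuration for the synthetic multi-experiment generator
#'
#' Builds and validates a simulation configuration. Defaults emulate the
#' five-reactor study design: per-sample richness 27-86 ASVs, cDNA
#' profiles, a first H2 injection at day 0, water refills shortly after
#' injection in four of five experiments, three injections in two of them,
#' and an engineered shared ASV pool for experiments 2-4.
#'
#' Each sample is composed of three layers: a persistent engineered shared
#' core (designated experiments only; drawn from a reserved block of the
#' global pool and assigned to H2-fed guilds), a persistent private part
#' that evolves with a small per-ASV turnover probability, and a transient
#' slice redrawn every sampling day (rare, flickering detections). The
#' transient slice makes each experiment's cumulative ASV pool realistically
#' larger than any single sample, which is what the richness-matched null
#' model sees.
#'
#' @param n_experiments Number of experiments (default 5).
#' @param richness_range Integer bounds on per-sample richness (default
#'   `c(27, 86)`).
#' @param shared_pool_fraction Fraction in `[0, 1]` of each designated
#'   experiment's ASVs drawn from the common reserved pool (default 0.6).
#' @param shared_experiments Experiment ids engineered to share a pool;
#'   default experiments 2-4 (clipped to `n_experiments`; empty when fewer
#'   than 3 experiments unless set explicitly).
#' @param fermenter_loss_prob Probability that a fermenter-guild ASV is
#'   lost after the first injection (default 0.45).
#' @param hydrogenotroph_boost Multiplicative abundance factor (>= 1)
#'   applied to sulfate-reducer and methanogen ASVs from day 0 on
#'   (default 5).
#' @param sampling_days,injections,refills Lists with one integer vector
#'   per experiment (negative days = before injection; first injection at
#'   day 0). Defaults mirror the study design and are recycled for other
#'   `n_experiments`.
#' @param guild_mix Named proportions over
#'   `c("fermentation", "sulfate_reduction", "methanogenesis",
#'   "wood_ljungdahl", "other")`, summing to 1.
#' @param pool_size Total ASV pool size (default 1000).
#' @param depth Multinomial sequencing depth per sample (default 10000).
#' @param turnover Per-ASV replacement probability per sampling step in the
#'   persistent private part (default 0.05).
#' @param transient_fraction Fraction of the private part redrawn fresh
#'   each day (default 0.50); controls how much larger an experiment's
#'   cumulative ASV pool is than any single sample.
#' @param abundance_sdlog Log-normal sd of per-ASV base abundances
#'   (default 1.5).
#' @param emit_dna Also emit a correlated DNA-labelled table carrying a
#'   persistent necromass ASV set (default FALSE; the analysis uses cDNA).
#' @param singleton_spike Number of singleton ASVs (total count 1) spiked
#'   into each experiment, for exercising the singleton filter (default 0).
#' @param seed Integer root seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_experiments = 5,
                       richness_range = c(27L, 86L),
                       shared_pool_fraction = 0.6,
                       shared_experiments = NULL,
                       fermenter_loss_prob = 0.45,
                       hydrogenotroph_boost = 5,
                       sampling_days = NULL,
                       injections = NULL,
                       refills = NULL,
                       guild_mix = c(fermentation = 0.40,
                                     sulfate_reduction = 0.25,
                                     methanogenesis = 0.10,
                                     wood_ljungdahl = 0.10,
                                     other = 0.15),
                       pool_size = 1000,
                       depth = 10000,
                       turnover = 0.05,
                       transient_fraction = 0.50,
                       abundance_sdlog = 1.5,
                       emit_dna = FALSE,
                       singleton_spike = 0,
                       seed = 1) {
  default_days <- list(c(-1L, 3L, 7L, 14L, 21L, 28L, 35L, 43L),
                       c(-8L, -1L, 4L, 9L, 15L, 21L, 28L),
                       c(-1L, 2L, 5L, 8L, 12L, 20L, 30L),
                       c(-1L, 2L, 5L, 9L, 14L, 21L),
                       c(-1L, 2L, 6L, 10L, 15L, 25L))
  default_inj <- list(0L, 0L, c(0L, 40L, 80L), 0L, c(0L, 35L, 70L))
  default_ref <- list(31L, integer(), 9L, 6L, 7L)
  recycle <- function(x, dflt) {
    x <- x %||% dflt
    if (!is.list(x)) x <- list(x)
    lapply(seq_len(n_experiments),
           function(i) as.integer(x[[(i - 1) %% length(x) + 1]]))
  }
  experiments <- paste0("exp", seq_len(n_experiments))
  if (is.null(shared_experiments)) {
    shared_experiments <-
      if (n_experiments >= 3) experiments[2:min(4, n_experiments)] else
        character()
  }
  cfg <- list(
    n_experiments = as.integer(n_experiments),
    experiments = experiments,
    richness_range = as.integer(richness_range),
    shared_pool_fraction = shared_pool_fraction,
    shared_experiments = as.character(shared_experiments),
    fermenter_loss_prob = fermenter_loss_prob,
    hydrogenotroph_boost = hydrogenotroph_boost,
    sampling_days = recycle(sampling_days, default_days),
    injections = recycle(injections, default_inj),
    refills = recycle(refills, default_ref),
    guild_mix = guild_mix,
    pool_size = as.integer(pool_size),
    depth = as.integer(depth),
    turnover = turnover,
    transient_fraction = transient_fraction,
    abundance_sdlog = abundance_sdlog,
    emit_dna = isTRUE(emit_dna),
    singleton_spike = as.integer(singleton_spike),
    seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  probs <- c(shared_pool_fraction = cfg$shared_pool_fraction,
             fermenter_loss_prob = cfg$fermenter_loss_prob,
             turnover = cfg$turnover,
             transient_fraction = cfg$transient_fraction)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    abort(paste0("probabilities/fractions must lie in [0, 1]: ",
                 paste(names(probs)[bad], collapse = ", ")))
  }
  if (cfg$hydrogenotroph_boost < 1) abort("hydrogenotroph_boost must be >= 1")
  if (abs(sum(cfg$guild_mix) - 1) > 1e-9) abort("guild_mix must sum to 1")
  if (any(cfg$guild_mix < 0)) abort("guild_mix proportions must be nonnegative")
  known <- c(names(guild_module_map), "other")
  if (!all(names(cfg$guild_mix) %in% known)) {
    abort(paste0("guild_mix names must be among: ",
                 paste(known, collapse = ", ")))
  }
  rr <- cfg$richness_range
  if (length(rr) != 2 || any(rr <= 0) || rr[1] > rr[2]) {
    abort("richness_range must be two positive integers with lower <= upper")
  }
  if (rr[2] > cfg$pool_size) {
    abort("richness bounds exceed the total ASV pool size")
  }
  shared_block <- ceiling(cfg$shared_pool_fraction * rr[2])
  if (rr[2] - floor(cfg$shared_pool_fraction * rr[1]) >
      cfg$pool_size - shared_block) {
    abort("richness bounds exceed the private pool size")
  }
  for (i in seq_len(cfg$n_experiments)) {
    d <- cfg$sampling_days[[i]]
    if (length(d) == 0 || any(diff(d) <= 0)) {
      abort(sprintf("sampling_days must be strictly increasing (experiment %d)",
                    i))
    }
    inj <- cfg$injections[[i]]
    if (length(inj) == 0 || inj[1] != 0L) {
      abort(sprintf("first injection day must be 0 (experiment %d)", i))
    }
  }
  if (!all(cfg$shared_experiments %in% cfg$experiments)) {
    abort("shared_experiments must be a subset of the experiment ids")
  }
  structure(cfg, class = "sim_config")
}

# genus names used for ASVs outside the annotated guilds
other_genera <- paste0("Aquiferibacterium_", sprintf("%02d", 1:15))

#' Simulate a multi-experiment ASV time-series dataset
#'
#' Deterministic given the config seed. Pool construction uses one child
#' seed and each experiment another (derived from its label), so adding an
#' experiment never perturbs the draws of the others. See [sim_config()]
#' for the community model.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `slime_dataset`: `community` (long tibble,
#'   all experiments), `taxonomy` (`asv_id`, `genus`), `guilds` (the guild
#'   annotation table used), `designs` (per-experiment event/sampling
#'   tibble), `events` (long event log), `truth` (engineered shared pairs),
#'   `config`.
#' @export
simulate_dataset <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- validate_sim_config(cfg)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)

  pool <- build_pool(cfg)
  community <- purrr::map_dfr(cfg$experiments, function(e)
    simulate_experiment(cfg, e, pool))

  used <- unique(community$asv_id)
  taxonomy <- dplyr::filter(pool$taxonomy, .data$asv_id %in% used)
  spikes <- setdiff(used, taxonomy$asv_id) # singleton-spike ASVs, if any
  if (length(spikes)) {
    taxonomy <- dplyr::bind_rows(
      taxonomy,
      tibble::tibble(asv_id = sort(spikes),
                     genus = other_genera[
                       (seq_along(spikes) - 1) %% length(other_genera) + 1]))
  }

  events <- purrr::map_dfr(seq_len(cfg$n_experiments), function(i) {
    e <- cfg$experiments[i]
    dplyr::bind_rows(
      tibble::tibble(experiment = e, event = "injection",
                     day = cfg$injections[[i]],
                     h2_percent = NA_real_),
      tibble::tibble(experiment = e, event = "refill",
                     day = cfg$refills[[i]], h2_percent = NA_real_))
  })
  designs <- tibble::tibble(
    experiment = cfg$experiments,
    injection_days = cfg$injections,
    refill_days = cfg$refills,
    sampling_days = cfg$sampling_days)

  truth <- if (length(cfg$shared_experiments) >= 2) {
    prs <- utils::combn(sort(cfg$shared_experiments), 2)
    tibble::tibble(experiment_a = prs[1, ], experiment_b = prs[2, ],
                   shared = TRUE)
  } else {
    tibble::tibble(experiment_a = character(), experiment_b = character(),
                   shared = logical())
  }

  structure(list(community = community, taxonomy = taxonomy,
                 guilds = default_guild_table(), designs = designs,
                 events = events, truth = truth, config = cfg),
            class = "slime_dataset")
}

# Global pool: ASV ids, guilds, genera. The first `shared_block` ASVs are
# reserved for the engineered shared community and assigned to H2-fed
# guilds (sulfate reduction / methanogenesis / Wood-Ljungdahl), so the
# convergent core survives the post-injection fermenter loss, as the
# convergent communities in H2-fed incubations do.
build_pool <- function(cfg) {
  set.seed(child_seed(cfg$seed, "pool"))
  p <- cfg$pool_size
  shared_block <- ceiling(cfg$shared_pool_fraction * cfg$richness_range[2])
  asv_id <- sprintf("ASV_%04d", seq_len(p))
  mix <- cfg$guild_mix
  all_guilds <- c(names(guild_module_map), "other")
  mix_full <- setNames(numeric(length(all_guilds)), all_guilds)
  mix_full[names(mix)] <- mix
  h2_guilds <- c("sulfate_reduction", "methanogenesis", "wood_ljungdahl")
  h2_mix <- mix_full[h2_guilds]
  if (sum(h2_mix) == 0) h2_mix[] <- 1
  guild <- character(p)
  if (shared_block > 0) {
    guild[seq_len(shared_block)] <- sample(h2_guilds, shared_block,
                                           replace = TRUE,
                                           prob = h2_mix / sum(h2_mix))
  }
  rest <- setdiff(seq_len(p), seq_len(shared_block))
  guild[rest] <- sample(all_guilds, length(rest), replace = TRUE,
                        prob = mix_full)
  gt <- default_guild_table()
  genus_by_guild <- split(gt$genus, gt$guild)
  genus <- vapply(guild, function(g) {
    if (g == "other") sample(other_genera, 1) else
      sample(genus_by_guild[[g]], 1)
  }, character(1), USE.NAMES = FALSE)
  list(asv_id = asv_id, guild = guild,
       shared_block = shared_block,
       taxonomy = tibble::tibble(asv_id = asv_id, genus = genus))
}

simulate_experiment <- function(cfg, e, pool) {
  set.seed(child_seed(cfg$seed, e))
  i <- match(e, cfg$experiments)
  days <- cfg$sampling_days[[i]]
  rr <- cfg$richness_range
  r_e <- if (rr[1] == rr[2]) rr[1] else sample(seq(rr[1], rr[2]), 1)
  engineered <- e %in% cfg$shared_experiments
  s_e <- if (engineered) round(cfg$shared_pool_fraction * r_e) else 0L
  shared_idx <- seq_len(s_e) # nested prefix of the reserved block
  private_pool <- setdiff(seq_len(cfg$pool_size),
                          seq_len(pool$shared_block))
  n_private <- r_e - s_e
  n_transient <- round(cfg$transient_fraction * n_private)
  n_core <- n_private - n_transient

  # per-(experiment, ASV) base abundance, log-normal dominance structure
  abund <- rlnorm(cfg$pool_size, meanlog = 0, sdlog = cfg$abundance_sdlog)

  # fermenter ASVs lost after the first injection (decided once)
  fermenters <- which(pool$guild == "fermentation")
  lost <- fermenters[runif(length(fermenters)) < cfg$fermenter_loss_prob]
  boosted <- pool$guild %in% c("sulfate_reduction", "methanogenesis")

  core <- sample(private_pool, n_core)
  rows <- vector("list", length(days))
  for (k in seq_along(days)) {
    day <- days[k]
    post <- day >= 0
    avail <- if (post) setdiff(private_pool, lost) else private_pool
    if (k > 1) {
      if (post) core <- setdiff(core, lost) # injection loss, no replacement
      turn <- runif(length(core)) < cfg$turnover
      if (any(turn)) {
        fresh <- sample(setdiff(avail, core), sum(turn))
        core <- c(core[!turn], fresh)
      }
    }
    transient <- if (n_transient > 0) {
      sample(setdiff(avail, core), n_transient)
    } else integer()
    present <- c(shared_idx, core, transient)
    w <- abund[present]
    if (post) w[boosted[present]] <- w[boosted[present]] *
        cfg$hydrogenotroph_boost
    counts <- draw_counts(w, cfg$depth)
    rows[[k]] <- tibble::tibble(
      experiment = e,
      sample_id = paste0(e, "_d", day),
      asv_id = pool$asv_id[present],
      count = counts, day = day, nucleic_acid = "cDNA")
  }
  out <- dplyr::bind_rows(rows)

  if (cfg$singleton_spike > 0) {
    spikes <- purrr::map_dfr(seq_len(cfg$singleton_spike), function(j) {
      k <- sample(length(days), 1)
      tibble::tibble(experiment = e,
                     sample_id = paste0(e, "_d", days[k]),
                     asv_id = sprintf("ASV_spike_%s_%02d", e, j),
                     count = 1L, day = days[k], nucleic_acid = "cDNA")
    })
    out <- dplyr::bind_rows(out, spikes)
  }

  if (cfg$emit_dna) {
    # DNA profile: the active community plus a persistent necromass set
    necromass <- sample(private_pool, min(15, length(private_pool)))
    dna <- purrr::map_dfr(seq_along(days), function(k) {
      pres <- unique(c(
        out$asv_id[out$sample_id == paste0(e, "_d", days[k]) &
                     !grepl("spike", out$asv_id)],
        pool$asv_id[necromass]))
      idx <- match(pres, pool$asv_id)
      tibble::tibble(experiment = e,
                     sample_id = paste0(e, "_dna_d", days[k]),
                     asv_id = pres,
                     count = draw_counts(abund[idx], cfg$depth),
                     day = days[k], nucleic_acid = "DNA")
    })
    out <- dplyr::bind_rows(out, dna)
  }
  out
}

# Multinomial resampling to exact depth with a detection floor: engineered
# presence is preserved by moving one count from the most abundant ASV to
# any ASV the multinomial draw zeroed out.
draw_counts <- function(w, depth) {
  counts <- as.integer(rmultinom(1, size = depth, prob = w)[, 1])
  zero <- which(counts == 0)
  if (length(zero)) {
    top <- which.max(counts)
    counts[top] <- counts[top] - length(zero)
    counts[zero] <- 1L
    if (counts[top] < 1L) abort("depth too small for the detection floor")
  }
  counts
}

#' @export
print.slime_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic SLiME dataset: %d experiments, %d samples, %d ASVs (seed %d)\n",
    length(unique(x$community$experiment)),
    length(unique(x$community$sample_id)),
    length(unique(x$community$asv_id)), x$config$seed))
  invisible(x)
}

#' Write a simulated dataset to flat files
#'
#' Emits one QIIME2-dialect feature table per experiment plus
#' `metadata.tsv`, `taxonomy.tsv`, `guilds.tsv` and `events.tsv`, all
#' re-readable with the package's readers.
#'
#' @param ds A `slime_dataset` from [simulate_dataset()].
#' @param directory Output directory (created if needed).
#' @param overwrite Overwrite existing files (default FALSE: refuses if any
#'   target file exists).
#' @return A manifest tibble `file`, `kind`, invisibly ordered as written.
#' @export
write_dataset <- function(ds, directory, overwrite = FALSE) {
  if (nrow(ds$community) == 0) abort("dataset has no samples")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  exps <- unique(ds$community$experiment)
  files <- c(
    setNames(file.path(directory,
                       paste0("feature_table_", exps, ".tsv")), exps),
    metadata = file.path(directory, "metadata.tsv"),
    taxonomy = file.path(directory, "taxonomy.tsv"),
    guilds = file.path(directory, "guilds.tsv"),
    events = file.path(directory, "events.tsv"))
  if (!overwrite && any(file.exists(files))) {
    abort(paste0("refusing to overwrite existing file(s): ",
                 paste(files[file.exists(files)], collapse = ", "),
                 " (set overwrite = TRUE)"))
  }
  manifest <- list()
  for (e in exps) {
    wide <- community_to_counts(
      dplyr::filter(ds$community, .data$experiment == e))
    write_feature_table(wide, files[[e]])
    manifest[[length(manifest) + 1]] <-
      tibble::tibble(file = files[[e]], kind = "feature_table",
                     experiment = e)
  }
  md <- ds$community |>
    dplyr::distinct(.data$sample_id, .data$experiment, .data$day,
                    .data$nucleic_acid)
  write_metadata(md, files[["metadata"]])
  write_taxonomy(ds$taxonomy, files[["taxonomy"]])
  write_guild_table(ds$guilds, files[["guilds"]])
  write_events(ds$events, files[["events"]])
  manifest <- dplyr::bind_rows(
    dplyr::bind_rows(manifest),
    tibble::tibble(file = unname(files[c("metadata", "taxonomy", "guilds",
                                         "events")]),
                   kind = c("metadata", "taxonomy", "guilds", "events"),
                   experiment = NA_character_))
  invisible(manifest)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param directory Directory containing `feature_table_*.tsv`,
#'   `metadata.tsv`, `taxonomy.tsv`, `guilds.tsv`, `events.tsv`.
#' @return A list with `community`, `taxonomy`, `guilds`, `designs`,
#'   `events` in the same shapes as [simulate_dataset()] output.
#' @export
read_dataset <- function(directory) {
  metadata <- read_metadata(file.path(directory, "metadata.tsv"))
  tabs <- list.files(directory, pattern = "^feature_table_.*\\.tsv$",
                     full.names = TRUE)
  if (!length(tabs)) abort(paste0("no feature tables found in ", directory))
  community <- purrr::map_dfr(tabs, function(f)
    as_community(read_feature_table(f), metadata))
  events <- read_events(file.path(directory, "events.tsv"))
  structure(list(
    community = community,
    taxonomy = read_taxonomy(file.path(directory, "taxonomy.tsv")),
    guilds = read_guild_table(file.path(directory, "guilds.tsv")),
    designs = experiment_designs(events, metadata),
    events = events,
    truth = NULL,
    config = NULL), class = "slime_dataset")
}
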