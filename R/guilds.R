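# Genus-level metabolic guild annotation, guild trajectories, core/shared
# communities across experiments, and the chord-diagram edge list.

guild_module_map <- c(methanogenesis = "M00567",
                      sulfate_reduction = "M00596",
                      wood_ljungdahl = "M00377",
                      fermentation = "FERM")

#' The guild annotation table shipped with the package
#'
#' Genus-to-guild assignments for the taxa recurrently observed in
#' H2-amended deep-aquifer incubations: sulfate reducers (dissimilatory
#' sulfate reduction, KEGG module M00596), hydrogenotrophic methanogens
#' (M00567), acetogens using the Wood-Ljungdahl pathway (M00377) and
#' fermenters (labelled FERM). The fermentation KO list is a configurable
#' stand-in — replace it with a curated enrichment list for real analyses.
#' The whole table is plain TSV and user-replaceable via
#' [read_guild_table()].
#'
#' @return Tibble `genus`, `guild`, `module`, `ko_ids` (semicolon-separated
#'   KO identifiers).
#' @export
default_guild_table <- function() {
  read_guild_table(system.file("extdata", "guild_annotations.tsv",
                               package = "slimediv", mustWork = TRUE))
}

#' Read/write a guild annotation table
#'
#' @param path TSV with columns `genus`, `guild`, `module`, `ko_ids`
#'   (semicolon-separated KOs). Guild/module pairings are validated against
#'   the fixed mapping M00567 = methanogenesis, M00596 = sulfate reduction,
#'   M00377 = Wood-Ljungdahl, FERM = fermentation.
#' @return Tibble `genus`, `guild`, `module`, `ko_ids`.
#' @export
read_guild_table <- function(path) {
  gt <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  needed <- c("genus", "guild", "module", "ko_ids")
  missing_cols <- setdiff(needed, names(gt))
  if (length(missing_cols)) {
    abort(paste0("guild table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_guild <- setdiff(unique(gt$guild), names(guild_module_map))
  if (length(bad_guild)) {
    abort(paste0("unknown guild(s): ", paste(bad_guild, collapse = ", ")))
  }
  mismatch <- gt$module != guild_module_map[gt$guild]
  if (any(mismatch)) {
    abort(paste0("guild/module mismatch for genus: ",
                 paste(gt$genus[mismatch], collapse = ", ")))
  }
  gt[needed]
}

#' @rdname read_guild_table
#' @param guild_table Tibble as returned by [read_guild_table()].
#' @export
write_guild_table <- function(guild_table, path) {
  readr::write_tsv(guild_table, path, progress = FALSE)
  invisible(path)
}

#' Annotate a community with genus and metabolic guild membership
#'
#' Joins each ASV to its genus (taxonomy must cover every ASV) and to the
#' set of guilds annotated for that genus. Genera absent from the guild
#' table are carried as unannotated (empty guild set). A genus may belong
#' to several guilds; downstream summaries dual-count such ASVs and say so.
#'
#' @param community Long community tibble.
#' @param taxonomy Tibble `asv_id`, `genus` covering all ASVs.
#' @param guild_table Tibble from [read_guild_table()] /
#'   [default_guild_table()]; may be partial or empty.
#' @return The community tibble with added `genus` and `guilds`
#'   (list-column of guild names, possibly empty).
#' @export
annotate_guilds <- function(community, taxonomy,
                            guild_table = default_guild_table()) {
  missing_asvs <- setdiff(unique(community$asv_id), taxonomy$asv_id)
  if (length(missing_asvs)) {
    abort(paste0("ASV(s) missing from taxonomy: ",
                 paste(utils::head(missing_asvs, 10), collapse = ", "),
                 if (length(missing_asvs) > 10) " ..."))
  }
  genus_guilds <- if (nrow(guild_table)) {
    guild_table |>
      dplyr::group_by(.data$genus) |>
      dplyr::summarise(guilds = list(unique(.data$guild)), .groups = "drop")
  } else {
    tibble::tibble(genus = character(), guilds = list())
  }
  community |>
    dplyr::left_join(taxonomy, by = "asv_id") |>
    dplyr::left_join(genus_guilds, by = "genus") |>
    dplyr::mutate(guilds = purrr::map(.data$guilds, ~ .x %||% character()))
}

#' Per-day guild composition of an annotated community
#'
#' Sums relative abundance per guild and day. ASVs annotated to several
#' guilds contribute their full weight to each guild (dual counting), so
#' guild fractions can exceed 1 in total when overlaps exist; the
#' `unannotated` fraction completes the per-day sum to 1 for single-guild
#' annotations.
#'
#' @param annotated Output of [annotate_guilds()].
#' @return Tibble `experiment`, `day`, `guild` (including `"unannotated"`),
#'   `fraction`.
#' @export
guild_trajectory <- function(annotated) {
  base <- annotated |>
    dplyr::group_by(.data$experiment, .data$day) |>
    dplyr::mutate(.total = sum(.data$count)) |>
    dplyr::ungroup()
  tagged <- base |>
    dplyr::mutate(guild = purrr::map(.data$guilds, function(g) {
      if (length(g)) g else "unannotated"
    })) |>
    tidyr::unnest("guild")
  all_guilds <- c(names(guild_module_map), "unannotated")
  tagged |>
    dplyr::group_by(.data$experiment, .data$day, .data$guild) |>
    dplyr::summarise(fraction = sum(.data$count / .data$.total),
                     .groups = "drop") |>
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("experiment"), !!rlang::sym("day")),
      guild = all_guilds, fill = list(fraction = 0)) |>
    dplyr::arrange(.data$experiment, .data$day, .data$guild)
}

#' Core (shared) community across experiments at one time category
#'
#' ASVs present (count > 0) in the category sample of every experiment in
#' scope, grouped by genus. Anti-monotone in scope: enlarging the scope can
#' only shrink the core.
#'
#' @param community Long community tibble (shared ASV namespace across
#'   experiments).
#' @param assignments Output of [assign_timepoints_all()].
#' @param category One of `"Before"`, `"After"`, `"Furthest"`.
#' @param scope Character vector of experiment ids (default: all in
#'   `assignments`).
#' @param taxonomy Optional tibble `asv_id`, `genus`; when given, the core
#'   is annotated and sorted by genus.
#' @return Tibble `asv_id` (and `genus` when taxonomy is given), one row per
#'   core ASV.
#' @export
core_community <- function(community, assignments, category,
                           scope = unique(assignments$experiment),
                           taxonomy = NULL) {
  pres <- presence_sets(community,
                        dplyr::filter(assignments,
                                      .data$category == .env$category,
                                      .data$experiment %in% scope))
  missing_exp <- setdiff(scope, pres$experiment)
  if (length(missing_exp)) {
    abort(paste0("category '", category, "' is not assigned for experiment(s): ",
                 paste(missing_exp, collapse = ", ")))
  }
  core <- Reduce(intersect, pres$asvs)
  out <- tibble::tibble(asv_id = core)
  if (!is.null(taxonomy)) {
    out <- out |>
      dplyr::left_join(taxonomy, by = "asv_id") |>
      dplyr::arrange(.data$genus, .data$asv_id)
  }
  out
}

#' Chord-diagram edge list: ASV x time point x KO
#'
#' One edge per (present ASV, time point, KO of the ASV's guild modules),
#' weighted by the ASV's relative abundance at that time point. Edges are
#' attribute fan-outs: every KO edge of one ASV at one time point carries
#' the same weight (weights are not split across KOs). Rows are ordered by
#' experiment, time point, genus, and decreasing weight within genus, as
#' circular layouts conventionally expect. Unannotated ASVs produce no
#' edges.
#'
#' @param annotated Output of [annotate_guilds()].
#' @param guild_table The guild table used for annotation (provides KO ids).
#' @return Tibble `experiment`, `timepoint_index`, `day`, `asv_id`, `genus`,
#'   `guild`, `ko_id`, `weight`.
#' @export
chord_edges <- function(annotated, guild_table = default_guild_table()) {
  if (nrow(annotated) == 0) abort("annotated community has no samples")
  kos <- guild_table |>
    dplyr::mutate(ko_id = strsplit(.data$ko_ids, ";", fixed = TRUE)) |>
    tidyr::unnest("ko_id") |>
    dplyr::distinct(.data$genus, .data$guild, .data$ko_id)
  weights <- annotated |>
    dplyr::group_by(.data$experiment, .data$day) |>
    dplyr::mutate(weight = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$experiment) |>
    dplyr::mutate(timepoint_index = match(.data$day, sort(unique(.data$day)))) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$count > 0)
  weights |>
    dplyr::inner_join(kos, by = "genus",
                      relationship = "many-to-many") |>
    dplyr::select("experiment", "timepoint_index", "day", "asv_id", "genus",
                  "guild", "ko_id", "weight") |>
    dplyr::arrange(.data$experiment, .data$timepoint_index, .data$genus,
                   dplyr::desc(.data$weight), .data$asv_id, .data$ko_id)
}
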