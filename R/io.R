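# Readers/writers for the flat-file interfaces (QIIME2-style feature table
# TSV, metadata, event log, taxonomy, guild table, chemistry series), plus
# the table-level filters and time-category alignment.

#' Build a long community tibble from a count table and sample metadata
#'
#' The community tibble is the package's central observational object: one
#' row per (sample, ASV) with a positive count, carrying the experiment id,
#' the day relative to the first H2 injection (day 0 = injection), and the
#' nucleic-acid type (DNA or cDNA).
#'
#' @param counts A wide count tibble as returned by [read_feature_table()]:
#'   first column `asv_id`, one integer column per sample.
#' @param metadata A tibble with columns `sample_id`, `experiment`, `day`,
#'   `nucleic_acid` covering every sample column of `counts`.
#' @return A long tibble with columns `experiment`, `sample_id`, `asv_id`,
#'   `count`, `day`, `nucleic_acid`; zero counts are dropped.
#' @export
as_community <- function(counts, metadata) {
  check_count_table(counts)
  needed <- c("sample_id", "experiment", "day", "nucleic_acid")
  missing_cols <- setdiff(needed, names(metadata))
  if (length(missing_cols)) {
    abort(paste0("metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  samples <- setdiff(names(counts), "asv_id")
  unknown <- setdiff(samples, metadata$sample_id)
  if (length(unknown)) {
    abort(paste0("samples absent from metadata: ",
                 paste(unknown, collapse = ", ")))
  }
  long <- tidyr::pivot_longer(counts, -"asv_id",
                              names_to = "sample_id", values_to = "count")
  empty <- setdiff(samples, unique(long$sample_id[long$count > 0]))
  if (length(empty)) {
    warn(paste0("dropping all-zero sample(s): ", paste(empty, collapse = ", ")))
  }
  long |>
    dplyr::filter(.data$count > 0) |>
    dplyr::inner_join(
      dplyr::select(metadata, dplyr::all_of(needed)), by = "sample_id") |>
    dplyr::select("experiment", "sample_id", "asv_id", "count", "day",
                  "nucleic_acid") |>
    dplyr::arrange(.data$experiment, .data$day, .data$sample_id)
}

#' Convert a long community tibble back to a wide count table
#'
#' @param community A long community tibble (see [as_community()]).
#' @return A wide tibble with `asv_id` first and one column per sample, in
#'   first-appearance order.
#' @export
community_to_counts <- function(community) {
  community |>
    dplyr::select("asv_id", "sample_id", "count") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0L)
}

check_count_table <- function(counts) {
  if (!"asv_id" %in% names(counts)) abort("count table must have an asv_id column")
  if (anyDuplicated(counts$asv_id)) {
    dup <- unique(counts$asv_id[duplicated(counts$asv_id)])
    abort(paste0("duplicated ASV id(s): ", paste(dup, collapse = ", ")))
  }
  samples <- setdiff(names(counts), "asv_id")
  if (anyDuplicated(samples)) abort("duplicated sample id(s) in header")
  for (s in samples) {
    v <- counts[[s]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) ||
        any(v != as.integer(round(v)))) {
      abort(paste0("non-integer or negative counts in sample column '", s, "'"))
    }
  }
  invisible(counts)
}

#' Read an ASV feature table
#'
#' Understands the QIIME2 `feature-table.tsv` export dialect: ASV ids in the
#' first column, sample ids in the header, an optional `#OTU ID` header token
#' and an optional leading `# Constructed from biom file` comment line. Files
#' ending in `.biom` are read through the biomformat package if installed.
#'
#' @param path Path to a TSV (or BIOM 2.x JSON/HDF5) feature table.
#' @return A wide count tibble: `asv_id` first, one integer column per sample.
#' @export
read_feature_table <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("reading BIOM files requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    out <- tibble::tibble(asv_id = rownames(m))
    out <- dplyr::bind_cols(out, tibble::as_tibble(m))
    return(check_count_table(dplyr::mutate(
      out, dplyr::across(-"asv_id", ~ as.integer(round(.x))))))
  }
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1], "# Constructed")) lines <- lines[-1]
  if (!length(lines)) abort(paste0("empty feature table: ", path))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] %in% c("#OTU ID", "#ASV ID", "asv_id", "OTU ID")) {
    header[1] <- "asv_id"
  } else {
    abort(paste0("malformed feature-table header: first field '", header[1],
                 "' (expected '#OTU ID' or 'asv_id')"))
  }
  body <- readr::read_tsv(I(lines[-1]), col_names = header,
                          col_types = readr::cols(
                            asv_id = readr::col_character(),
                            .default = readr::col_double()),
                          progress = FALSE)
  check_count_table(body)
  dplyr::mutate(body, dplyr::across(-"asv_id", as.integer))
}

#' Write an ASV feature table in the QIIME2 TSV dialect
#'
#' @param counts Wide count tibble (`asv_id` + sample columns).
#' @param path Output path.
#' @param otu_header Use the `#OTU ID` header token (default) instead of
#'   `asv_id`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(counts, path, otu_header = TRUE) {
  check_count_table(counts)
  out <- counts
  if (otu_header) names(out)[names(out) == "asv_id"] <- "#OTU ID"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read/write sample metadata
#'
#' Metadata is a TSV with columns `sample-id` (or `sample_id`), `experiment`,
#' `day` and `nucleic_acid`.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble with columns `sample_id`, `experiment`, `day`,
#'   `nucleic_acid`.
#' @export
read_metadata <- function(path) {
  md <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(md)[names(md) == "sample-id"] <- "sample_id"
  needed <- c("sample_id", "experiment", "day", "nucleic_acid")
  missing_cols <- setdiff(needed, names(md))
  if (length(missing_cols)) {
    abort(paste0("metadata missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dplyr::mutate(md[needed], experiment = as.character(.data$experiment),
                day = as.integer(.data$day))
}

#' @rdname read_metadata
#' @param metadata Tibble as returned by [read_metadata()].
#' @export
write_metadata <- function(metadata, path) {
  out <- metadata
  names(out)[names(out) == "sample_id"] <- "sample-id"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read/write the experiment event log
#'
#' The event log records H2 injections and water refills: TSV columns
#' `experiment`, `event` (`injection` or `refill`), `day`, optional
#' `h2_percent`.
#'
#' @param path Path to the event-log TSV.
#' @return A tibble `experiment`, `event`, `day`, `h2_percent`.
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  needed <- c("experiment", "event", "day")
  missing_cols <- setdiff(needed, names(ev))
  if (length(missing_cols)) {
    abort(paste0("event log missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(ev$event), c("injection", "refill"))
  if (length(bad)) {
    abort(paste0("unknown event type(s): ", paste(bad, collapse = ", ")))
  }
  if (!"h2_percent" %in% names(ev)) ev$h2_percent <- NA_real_
  dplyr::mutate(ev[c(needed, "h2_percent")],
                experiment = as.character(.data$experiment),
                day = as.integer(.data$day))
}

#' @rdname read_events
#' @param events Tibble as returned by [read_events()].
#' @export
write_events <- function(events, path) {
  readr::write_tsv(events, path, progress = FALSE)
  invisible(path)
}

#' Read/write the ASV taxonomy table (ASV id to genus)
#'
#' @param path Path to a TSV with columns `asv_id`, `genus`.
#' @return A tibble `asv_id`, `genus`.
#' @export
read_taxonomy <- function(path) {
  tx <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("asv_id", "genus") %in% names(tx))) {
    abort("taxonomy must have columns asv_id and genus")
  }
  if (anyDuplicated(tx$asv_id)) {
    abort(paste0("duplicated ASV id(s) in taxonomy: ",
                 paste(unique(tx$asv_id[duplicated(tx$asv_id)]),
                       collapse = ", ")))
  }
  tx[c("asv_id", "genus")]
}

#' @rdname read_taxonomy
#' @param taxonomy Tibble as returned by [read_taxonomy()].
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(taxonomy, path, progress = FALSE)
  invisible(path)
}

#' Build per-experiment designs from an event log and sampling days
#'
#' @param events Event-log tibble ([read_events()]).
#' @param metadata Sample metadata ([read_metadata()]); sampling days are
#'   taken from it per experiment.
#' @return A tibble with one row per experiment: `experiment`,
#'   `injection_days`, `refill_days`, `sampling_days` (list-columns).
#' @export
experiment_designs <- function(events, metadata) {
  samp <- metadata |>
    dplyr::distinct(.data$experiment, .data$day) |>
    dplyr::group_by(.data$experiment) |>
    dplyr::summarise(sampling_days = list(sort(unique(.data$day))),
                     .groups = "drop")
  ev <- events |>
    dplyr::group_by(.data$experiment) |>
    dplyr::summarise(
      injection_days = list(sort(.data$day[.data$event == "injection"])),
      refill_days = list(sort(.data$day[.data$event == "refill"])),
      .groups = "drop")
  out <- dplyr::left_join(samp, ev, by = "experiment") |>
    dplyr::mutate(
      injection_days = purrr::map(.data$injection_days, ~ .x %||% integer()),
      refill_days = purrr::map(.data$refill_days, ~ .x %||% integer()))
  bad <- purrr::map_lgl(out$injection_days,
                        ~ length(.x) == 0 || .x[1] != 0L)
  if (any(bad)) {
    abort(paste0("first injection day must be 0 for experiment(s): ",
                 paste(out$experiment[bad], collapse = ", ")))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove singleton ASVs from a community
#'
#' Drops, within each experiment table, every ASV whose total count across
#' all of that experiment's samples equals 1 (sequencing singletons). The
#' filter is applied per experiment, not across experiments, and is
#' idempotent.
#'
#' @param community Long community tibble.
#' @return The filtered community tibble.
#' @export
remove_singletons <- function(community) {
  out <- community |>
    dplyr::group_by(.data$experiment, .data$asv_id) |>
    dplyr::mutate(.total = sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$.total != 1L) |>
    dplyr::select(-".total")
  if (nrow(out) == 0 && nrow(community) > 0) {
    warn("all ASVs were singletons; the filtered community is empty")
  }
  out
}

#' Assign samples to the Before / After / Furthest time categories
#'
#' Categories relative to the first H2 injection (day 0):
#' * **Before** — the latest sample with day < 0;
#' * **After** — the earliest sample with day >= 0;
#' * **Furthest** — the latest post-injection sample strictly before the
#'   next perturbation (second injection or first post-injection refill),
#'   or the last sample if no such event exists. After and Furthest may
#'   coincide.
#'
#' @param samples Tibble with columns `sample_id` and `day` (one experiment),
#'   e.g. `dplyr::distinct(community, sample_id, day)`.
#' @param design One row of [experiment_designs()] or a list with
#'   `injection_days` and `refill_days`.
#' @return Tibble `category`, `sample_id`, `day`; categories without an
#'   eligible sample are omitted (with a warning for a missing Before).
#' @export
assign_timepoints <- function(samples, design) {
  days <- samples$day
  inj <- sort(unlist(design$injection_days))
  ref <- sort(unlist(design$refill_days))
  pick <- function(idx, which_end) {
    if (!length(idx)) return(NULL)
    i <- if (which_end == "max") idx[which.max(days[idx])] else
      idx[which.min(days[idx])]
    tibble::tibble(sample_id = samples$sample_id[i], day = days[i])
  }
  before <- pick(which(days < 0), "max")
  after <- pick(which(days >= 0), "min")
  cutoff <- suppressWarnings(min(c(inj[inj > 0], ref[ref > 0])))
  furthest_idx <- which(days >= 0 & days < cutoff)
  if (!length(furthest_idx)) furthest_idx <- which(days >= 0)
  furthest <- pick(furthest_idx, "max")
  if (is.null(before)) warn("no pre-injection sample; Before category omitted")
  out <- dplyr::bind_rows(
    if (!is.null(before)) dplyr::mutate(before, category = "Before"),
    if (!is.null(after)) dplyr::mutate(after, category = "After"),
    if (!is.null(furthest)) dplyr::mutate(furthest, category = "Furthest"))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(category = character(), sample_id = character(),
                          day = integer()))
  }
  dplyr::select(out, "category", "sample_id", "day")
}

#' Time-category assignments for every experiment of a community
#'
#' @param community Long community tibble.
#' @param designs Tibble from [experiment_designs()].
#' @return Tibble `experiment`, `category`, `sample_id`, `day`.
#' @export
assign_timepoints_all <- function(community, designs) {
  purrr::map_dfr(designs$experiment, function(e) {
    samples <- community |>
      dplyr::filter(.data$experiment == e) |>
      dplyr::distinct(.data$sample_id, .data$day)
    d <- designs[designs$experiment == e, ]
    dplyr::mutate(assign_timepoints(samples, d), experiment = e,
                  .before = 1)
  })
}

#' Read a long-format chemistry series
#'
#' @param path TSV with columns `analyte`, `day`, `measured`, `removed`
#'   (molar quantities; `removed` is the amount withdrawn at that sampling).
#' @return A tibble with those columns.
#' @export
read_chem_series <- function(path) {
  ch <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  needed <- c("analyte", "day", "measured", "removed")
  missing_cols <- setdiff(needed, names(ch))
  if (length(missing_cols)) {
    abort(paste0("chemistry series missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ch[needed]
}

#' Correct a chemistry time series for sampling loss
#'
#' Each sampling withdraws material from the closed reactor before the
#' remaining amount is measured; the corrected series adds back the
#' cumulative amount removed at all sampling events up to and including the
#' current one, so a non-reacting analyte appears constant:
#' `corrected(t_k) = measured(t_k) + sum_{j<=k} removed(t_j)`.
#'
#' @param chem Tibble with columns `analyte`, `day`, `measured`, `removed`.
#' @return The input with an added `corrected` column, ordered by analyte
#'   and day.
#' @export
correct_sampling_loss <- function(chem) {
  if (any(chem$removed < 0)) abort("negative removal amounts are not allowed")
  chem |>
    dplyr::arrange(.data$analyte, .data$day) |>
    dplyr::group_by(.data$analyte) |>
    dplyr::mutate(corrected = .data$measured + cumsum(.data$removed)) |>
    dplyr::ungroup()
}
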