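# Per-sample alpha diversity: richness, Stoddart (inverse Simpson),
# Shannon, Pielou, and trajectories over time.

#' Alpha diversity indices for a single sample
#'
#' `richness()` counts ASVs with a positive count. `stoddart()` is the
#' reciprocal of Simpson's concentration, `1 / sum(p_i^2)` (Stoddart &
#' Taylor's genotypic diversity, the usual reading of "an analog of the
#' Simpson index"); a Gini-Simpson variant `1 - sum(p_i^2)` is available via
#' `type`. `shannon()` is `-sum(p_i log p_i)` with the natural logarithm and
#' `pielou()` is `shannon / log(richness)`, so a uniform community has
#' Pielou evenness exactly 1.
#'
#' All indices are computed on relative abundances, so they are invariant to
#' scaling a sample's counts by a positive constant.
#'
#' @param counts Nonnegative numeric vector of ASV counts for one sample.
#' @param type For `stoddart()`: `"inverse"` (default, `1/sum(p^2)`) or
#'   `"gini"` (`1 - sum(p^2)`).
#' @return A single number. `pielou()` returns `NA` (with a warning) for
#'   samples with fewer than two ASVs, where evenness is undefined.
#' @export
#' @examples
#' richness(c(4, 0, 1, 2)) # 3
#' stoddart(c(2, 1, 1))    # 8/3
#' shannon(c(1, 1, 1, 1))  # log(4)
richness <- function(counts) {
  check_counts(counts, allow_zero = TRUE)
  n <- sum(counts > 0)
  if (n == 0) warn("all-zero sample: richness is 0")
  as.integer(n)
}

#' @rdname richness
#' @export
stoddart <- function(counts, type = c("inverse", "gini")) {
  type <- match.arg(type)
  p <- rel_abund(counts)
  conc <- sum(p^2)
  if (type == "inverse") 1 / conc else 1 - conc
}

#' @rdname richness
#' @export
shannon <- function(counts) {
  p <- rel_abund(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' @rdname richness
#' @export
pielou <- function(counts) {
  s <- sum(counts > 0)
  if (s < 2) {
    warn("Pielou evenness is undefined for samples with fewer than 2 ASVs")
    return(NA_real_)
  }
  shannon(counts) / log(s)
}

check_counts <- function(counts, allow_zero = FALSE) {
  if (!is.numeric(counts) || any(is.na(counts)) || any(counts < 0)) {
    abort("counts must be a nonnegative numeric vector without NAs")
  }
  if (!allow_zero && sum(counts) == 0) {
    abort("diversity is undefined for an all-zero sample")
  }
  invisible(counts)
}

rel_abund <- function(counts) {
  check_counts(counts)
  counts / sum(counts)
}

#' Alpha-diversity trajectories for every sample of a community
#'
#' Computes the requested indices per sample and returns them in long
#' format, ordered by experiment and day, ready for plotting against the
#' injection/refill event log.
#'
#' @param community Long community tibble (see [as_community()]).
#' @param indices Character vector among `"richness"`, `"stoddart"`,
#'   `"shannon"`, `"pielou"`.
#' @param stoddart_type Passed to [stoddart()].
#' @return Tibble `experiment`, `sample_id`, `day`, `index`, `value`.
#' @export
alpha_diversity <- function(community,
                            indices = c("richness", "stoddart", "shannon",
                                        "pielou"),
                            stoddart_type = "inverse") {
  indices <- match.arg(indices, several.ok = TRUE)
  fns <- list(
    richness = function(x) as.numeric(richness(x)),
    stoddart = function(x) stoddart(x, type = stoddart_type),
    shannon = shannon,
    pielou = pielou)
  community |>
    dplyr::group_by(.data$experiment, .data$sample_id, .data$day) |>
    dplyr::summarise(counts = list(.data$count), .groups = "drop") |>
    tidyr::crossing(index = indices) |>
    dplyr::mutate(value = purrr::map2_dbl(
      .data$counts, .data$index, ~ fns[[.y]](.x))) |>
    dplyr::select("experiment", "sample_id", "day", "index", "value") |>
    dplyr::arrange(.data$experiment, .data$day, .data$index)
}
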