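# Incidence-based (Jaccard) beta diversity between experiments, the
# mock-community null model, z-score normalization, convergence-pattern
# classification, and the time-differential bias check.

#' Jaccard dissimilarity between two presence sets
#'
#' `1 - |A intersect B| / |A union B|` on ASV identity sets (presence /
#' absence; abundances are ignored). Symmetric, in `[0, 1]`.
#'
#' @param a,b Character (or integer) vectors of ASV ids present in each
#'   community; duplicates are ignored.
#' @return The Jaccard dissimilarity.
#' @export
#' @examples
#' jaccard_dissimilarity(c("x", "y", "z"), c("y", "z", "w")) # 0.5
jaccard_dissimilarity <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    abort("Jaccard dissimilarity is undefined for two empty sets")
  }
  i <- sum(match(a, b, nomatch = 0L) > 0L)
  1 - i / (length(a) + length(b) - i)
}

#' Extract per-(experiment, category) presence sets
#'
#' @param community Long community tibble.
#' @param assignments Time-category assignments from
#'   [assign_timepoints_all()].
#' @return Tibble `experiment`, `category`, `sample_id`, `day`, `asvs`
#'   (list-column of present ASV ids).
#' @export
presence_sets <- function(community, assignments) {
  pres <- community |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$experiment, .data$sample_id) |>
    dplyr::summarise(asvs = list(unique(.data$asv_id)), .groups = "drop")
  assignments |>
    dplyr::inner_join(pres, by = c("experiment", "sample_id"))
}

#' Build the mock-community null distribution for one experiment pair
#'
#' Pools the two experiments' total observed ASV sets (union over all their
#' samples, regardless of time), then draws `n_mock` mock communities, each
#' a uniform without-replacement subset of the pooled ASVs whose richness
#' alternates between `richness_a` and `richness_b` (matching the observed
#' richness of the two real samples being compared). Consecutive draws are
#' paired disjointly — communities `2k-1` and `2k` form pair `k` — and the
#' Jaccard dissimilarity of the first `n_pairs` pairs forms the null
#' distribution; surplus communities are discarded. Deterministic given
#' `seed`.
#'
#' @param pool_a,pool_b ASV id vectors: the total observed pool of each
#'   experiment.
#' @param richness_a,richness_b Mock-community richness for each side.
#' @param n_mock Number of mock communities to draw (default 10000).
#' @param n_pairs Number of disjoint pairs to keep (default 1000; requires
#'   `2 * n_pairs <= n_mock`).
#' @param seed Integer seed.
#' @param pair Optional label for the experiment pair (bookkeeping only).
#' @return An object of class `null_distribution`: a list with `draws`
#'   (length `n_pairs`), `mean`, `sd`, `n_mock`, `n_pairs`, `pool_size`,
#'   `richness`, `seed`, `pair` and `degenerate` (TRUE when all draws are
#'   identical, i.e. `sd == 0`). Has [tidy()] and [glance()] methods.
#' @export
build_null <- function(pool_a, pool_b, richness_a, richness_b,
                       n_mock = 10000, n_pairs = 1000, seed = 1,
                       pair = NA_character_) {
  pool <- union(unique(pool_a), unique(pool_b))
  p <- length(pool)
  if (richness_a < 1 || richness_b < 1) {
    abort("mock richness must be at least 1")
  }
  if (richness_a > p || richness_b > p) {
    abort(sprintf("mock richness (%d, %d) exceeds pooled ASV count (%d)",
                  richness_a, richness_b, p))
  }
  if (2 * n_pairs > n_mock) {
    abort("n_pairs must not exceed n_mock / 2")
  }
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  # mock communities as index subsets of the pooled identity list;
  # identities do not affect Jaccard so indices suffice
  rich <- rep(c(richness_a, richness_b), length.out = n_mock)
  mocks <- lapply(rich, function(r) sample.int(p, r))
  draws <- vapply(seq_len(n_pairs), function(k) {
    x <- mocks[[2 * k - 1]]
    y <- mocks[[2 * k]]
    i <- sum(match(x, y, nomatch = 0L) > 0L)
    1 - i / (length(x) + length(y) - i)
  }, numeric(1))
  m <- mean(draws)
  s <- stats::sd(draws)
  structure(list(pair = pair, draws = draws, mean = m, sd = s,
                 n_mock = as.integer(n_mock), n_pairs = as.integer(n_pairs),
                 pool_size = p, richness = c(richness_a, richness_b),
                 seed = as.integer(seed), degenerate = isTRUE(s == 0)),
            class = "null_distribution")
}

.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "Mock-community null distribution%s\n  pool %d ASVs, richness (%d, %d), %d pairs from %d mocks\n  mean %.4f, sd %.4f%s\n",
    if (is.na(x$pair)) "" else paste0(" [", x$pair, "]"),
    x$pool_size, x$richness[1], x$richness[2], x$n_pairs, x$n_mock,
    x$mean, x$sd, if (x$degenerate) " (degenerate: sd = 0)" else ""))
  invisible(x)
}

#' @export
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$draws), jaccard = x$draws)
}

#' @export
glance.null_distribution <- function(x, ...) {
  tibble::tibble(pair = x$pair, mean = x$mean, sd = x$sd,
                 n_mock = x$n_mock, n_pairs = x$n_pairs,
                 pool_size = x$pool_size, richness_a = x$richness[1],
                 richness_b = x$richness[2], degenerate = x$degenerate)
}

#' Normalize an observed Jaccard dissimilarity against a null distribution
#'
#' `z = (observed - null mean) / null sd`. `significant` flags departures
#' from the central 95% band (`|z| > threshold`, strict); substantive
#' convergence calls use the lower tail (`z < -threshold`) only, since a
#' negative z means the pair shares more ASVs than random assembly from the
#' pooled biodiversity predicts.
#'
#' @param observed Observed Jaccard dissimilarity in `[0, 1]`.
#' @param null A `null_distribution` from [build_null()].
#' @param threshold Significance band half-width (default 1.96).
#' @return A one-row tibble `observed_jaccard`, `null_mean`, `null_sd`, `z`,
#'   `significant`, `reason` (`NA` unless z is undefined because the null is
#'   degenerate).
#' @export
beta_zscore <- function(observed, null, threshold = 1.96) {
  if (null$degenerate || null$sd == 0) {
    return(tibble::tibble(observed_jaccard = observed, null_mean = null$mean,
                          null_sd = null$sd, z = NA_real_,
                          significant = NA, reason = "degenerate_null"))
  }
  z <- (observed - null$mean) / null$sd
  # strict inequality at the band edge, robust to floating-point rounding
  tibble::tibble(observed_jaccard = observed, null_mean = null$mean,
                 null_sd = null$sd, z = z,
                 significant = abs(z) - threshold > 1e-9,
                 reason = NA_character_)
}

#' Classify the convergence pattern of one experiment pair
#'
#' Operationalizes the four qualitative dynamics of z-score-normalized beta
#' diversity over the Before / After / Furthest categories, with
#' significance defined on the lower tail (`z < -threshold`: the pair is
#' less dissimilar than the null expects):
#'
#' * `persistent_convergence` — significant at all three categories;
#' * `progressive_convergence` — not significant Before, significant
#'   Furthest;
#' * `transient_convergence` — not significant Before, significant After,
#'   not significant Furthest;
#' * `null_like` — otherwise. Combinations outside the four narrative cases
#'   (e.g. significant Before only) also map to `null_like` and are flagged
#'   `atypical`.
#'
#' Precedence: persistent > progressive > transient > null_like. Missing
#' categories are treated as not significant and flagged `partial`.
#'
#' @param z_before,z_after,z_furthest z-scores (may be `NA`).
#' @param threshold Lower-tail threshold (default 1.96).
#' @return One-row tibble `label`, `atypical`, `partial`.
#' @export
#' @examples
#' classify_pattern(0.09, -1.30, -3.58)  # progressive_convergence
#' classify_pattern(-0.67, -3.39, -0.32) # transient_convergence
classify_pattern <- function(z_before, z_after, z_furthest,
                             threshold = 1.96) {
  zs <- c(before = z_before, after = z_after, furthest = z_furthest)
  partial <- any(is.na(zs))
  sig <- !is.na(zs) & (-zs - threshold > 1e-9)
  label <- if (sig[["before"]] && sig[["after"]] && sig[["furthest"]]) {
    "persistent_convergence"
  } else if (!sig[["before"]] && sig[["furthest"]]) {
    "progressive_convergence"
  } else if (!sig[["before"]] && sig[["after"]] && !sig[["furthest"]]) {
    "transient_convergence"
  } else {
    "null_like"
  }
  atypical <- label == "null_like" && any(sig)
  tibble::tibble(label = label, atypical = atypical, partial = partial)
}

#' Pairwise between-experiment beta diversity with null normalization
#'
#' For every unordered pair of experiments and every time category assigned
#' in both, computes the observed Jaccard dissimilarity between the two
#' category samples and its z-score against a mock-community null built
#' from the pair's pooled ASVs (all samples, regardless of time) with mock
#' richness matched to the two observed samples. Each (pair, category) null
#' uses a child seed derived from the pair label, so adding experiments
#' never perturbs existing results.
#'
#' @param community Long community tibble (typically cDNA, singleton-filtered).
#' @param assignments Output of [assign_timepoints_all()].
#' @param n_mock,n_pairs Null-model size (see [build_null()]).
#' @param seed Root seed.
#' @param threshold Significance band half-width.
#' @param keep_nulls Keep the `null_distribution` objects in a list-column
#'   (default FALSE).
#' @return Tibble with one row per (pair, category): `experiment_a`,
#'   `experiment_b`, `pair`, `category`, `day_a`, `day_b`, `richness_a`,
#'   `richness_b`, `observed_jaccard`, `null_mean`, `null_sd`, `z`,
#'   `significant`, `reason`.
#' @export
pairwise_beta <- function(community, assignments, n_mock = 10000,
                          n_pairs = 1000, seed = 1, threshold = 1.96,
                          keep_nulls = FALSE) {
  pres <- presence_sets(community, assignments)
  pools <- community |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$experiment) |>
    dplyr::summarise(pool = list(unique(.data$asv_id)), .groups = "drop")
  exps <- sort(unique(assignments$experiment))
  if (length(exps) < 2) abort("need at least two experiments")
  pairs <- utils::combn(exps, 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    lab <- pair_label(a, b)
    pool_a <- pools$pool[[match(a, pools$experiment)]]
    pool_b <- pools$pool[[match(b, pools$experiment)]]
    cats <- intersect(pres$category[pres$experiment == a],
                      pres$category[pres$experiment == b])
    purrr::map_dfr(cats, function(cat) {
      pa <- pres[pres$experiment == a & pres$category == cat, ]
      pb <- pres[pres$experiment == b & pres$category == cat, ]
      sa <- pa$asvs[[1]]; sb <- pb$asvs[[1]]
      nd <- build_null(pool_a, pool_b, length(sa), length(sb),
                       n_mock = n_mock, n_pairs = n_pairs,
                       seed = child_seed(seed, paste0(lab, ":", cat)),
                       pair = lab)
      res <- beta_zscore(jaccard_dissimilarity(sa, sb), nd, threshold)
      out <- dplyr::bind_cols(
        tibble::tibble(experiment_a = a, experiment_b = b,
                       pair = paste(a, b, sep = "-"), category = cat,
                       day_a = pa$day[1], day_b = pb$day[1],
                       richness_a = length(sa), richness_b = length(sb)),
        res)
      if (keep_nulls) out$null <- list(nd)
      out
    })
  })
  rows$category <- factor(rows$category,
                          levels = c("Before", "After", "Furthest"))
  dplyr::arrange(rows, .data$pair, .data$category)
}

#' Classify convergence patterns for all pairs of a beta-diversity table
#'
#' @param beta Output of [pairwise_beta()].
#' @param threshold Lower-tail threshold.
#' @return Tibble `pair`, `experiment_a`, `experiment_b`, `z_before`,
#'   `z_after`, `z_furthest`, `label`, `atypical`, `partial`.
#' @export
classify_patterns <- function(beta, threshold = 1.96) {
  beta |>
    dplyr::group_by(.data$pair, .data$experiment_a, .data$experiment_b) |>
    dplyr::summarise(
      z_before = .data$z[match("Before", .data$category)],
      z_after = .data$z[match("After", .data$category)],
      z_furthest = .data$z[match("Furthest", .data$category)],
      .groups = "drop") |>
    dplyr::mutate(purrr::pmap_dfr(
      list(.data$z_before, .data$z_after, .data$z_furthest),
      classify_pattern, threshold = threshold))
}

#' Within-experiment beta diversity against the experiment's own null
#'
#' Jaccard dissimilarity and z-score for consecutive samples (by day) of one
#' experiment, normalized against a null built from that experiment's own
#' total ASV pool with richness matched to the two samples. With
#' `consecutive = FALSE` all sample pairs are compared.
#'
#' @param community Long community tibble.
#' @param n_mock,n_pairs,seed,threshold As in [pairwise_beta()].
#' @param consecutive Compare consecutive samples only (default) or all
#'   pairs.
#' @return Tibble `experiment`, `sample_a`, `sample_b`, `day_a`, `day_b`,
#'   `observed_jaccard`, `null_mean`, `null_sd`, `z`, `significant`,
#'   `reason`.
#' @export
within_experiment_beta <- function(community, n_mock = 10000, n_pairs = 1000,
                                   seed = 1, threshold = 1.96,
                                   consecutive = TRUE) {
  purrr::map_dfr(sort(unique(community$experiment)), function(e) {
    comm <- dplyr::filter(community, .data$experiment == e,
                          .data$count > 0)
    samp <- comm |>
      dplyr::distinct(.data$sample_id, .data$day) |>
      dplyr::arrange(.data$day)
    if (nrow(samp) < 2) {
      return(tibble::tibble())
    }
    pool <- unique(comm$asv_id)
    sets <- split(comm$asv_id, comm$sample_id)
    idx <- if (consecutive) {
      lapply(seq_len(nrow(samp) - 1), function(i) c(i, i + 1))
    } else {
      utils::combn(nrow(samp), 2, simplify = FALSE)
    }
    purrr::map_dfr(idx, function(ij) {
      sa <- sets[[samp$sample_id[ij[1]]]]
      sb <- sets[[samp$sample_id[ij[2]]]]
      lab <- paste0("within:", e, ":", samp$sample_id[ij[1]], "|",
                    samp$sample_id[ij[2]])
      nd <- build_null(pool, pool, length(unique(sa)), length(unique(sb)),
                       n_mock = n_mock, n_pairs = n_pairs,
                       seed = child_seed(seed, lab),
                       pair = paste0(e, " (within)"))
      dplyr::bind_cols(
        tibble::tibble(experiment = e,
                       sample_a = samp$sample_id[ij[1]],
                       sample_b = samp$sample_id[ij[2]],
                       day_a = samp$day[ij[1]], day_b = samp$day[ij[2]]),
        beta_zscore(jaccard_dissimilarity(sa, sb), nd, threshold))
    })
  })
}

#' Spearman check for time-differential bias in normalized beta diversity
#'
#' Samples compared at "equivalent" times are rarely taken on identical
#' days; if the day gap between the two sides of a pair drove the z-score,
#' the normalization would be biased. This runs a two-sided Spearman rank
#' correlation between `|day_a - day_b|` and z.
#'
#' @param beta Output of [pairwise_beta()] (needs `z`, `day_a`, `day_b`),
#'   or any tibble with columns `z` and `day_gap`.
#' @param alpha Flagging level (default 0.05).
#' @return One-row tibble `n`, `rho`, `p_value`, `biased` (`TRUE` when
#'   `p <= alpha`).
#' @export
time_differential_bias_check <- function(beta, alpha = 0.05) {
  gap <- if ("day_gap" %in% names(beta)) beta$day_gap else
    abs(beta$day_a - beta$day_b)
  ok <- !is.na(beta$z) & !is.na(gap)
  z <- beta$z[ok]
  gap <- gap[ok]
  if (length(z) < 5) {
    abort("need at least 5 pairs with defined z and day gap")
  }
  if (length(unique(gap)) == 1 || length(unique(z)) == 1) {
    return(tibble::tibble(n = length(z), rho = NA_real_,
                          p_value = NA_real_, biased = NA))
  }
  ct <- suppressWarnings(
    stats::cor.test(gap, z, method = "spearman", alternative = "two.sided"))
  tibble::tibble(n = length(z), rho = unname(ct$estimate),
                 p_value = ct$p.value, biased = ct$p.value <= alpha)
}
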