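test_that("Jaccard dissimilarity matches set enumeration and is symmetric", {
  expect_equal(jaccard_dissimilarity(c("x", "y"), c("x", "y")), 0)
  expect_equal(jaccard_dissimilarity(c("x", "y"), c("a", "b")), 1)
  expect_equal(jaccard_dissimilarity(c("x", "y", "z"), c("y", "z", "w")), 0.5)
  expect_error(jaccard_dissimilarity(character(), character()), "empty")

  set.seed(3)
  u <- letters[1:10]
  for (i in 1:30) {
    a <- sample(u, sample(1:10, 1))
    b <- sample(u, sample(1:10, 1))
    expect_equal(jaccard_dissimilarity(a, b), jaccard_oracle(u, a, b))
    expect_equal(jaccard_dissimilarity(a, b), jaccard_dissimilarity(b, a))
  }
})

test_that("Jaccard agrees with vegan's binary distance", {
  skip_if_not_installed("vegan")
  set.seed(5)
  u <- paste0("t", 1:12)
  for (i in 1:10) {
    a <- sample(u, sample(2:12, 1))
    b <- sample(u, sample(2:12, 1))
    m <- rbind(as.integer(u %in% a), as.integer(u %in% b))
    expect_equal(jaccard_dissimilarity(a, b),
                 as.numeric(vegan::vegdist(m, "jaccard", binary = TRUE)))
  }
})

test_that("build_null is deterministic, seeded, and leaves the RNG alone", {
  pool <- paste0("A", 1:30)
  n1 <- build_null(pool[1:20], pool[11:30], 8, 10, n_mock = 200,
                   n_pairs = 100, seed = 9)
  n2 <- build_null(pool[1:20], pool[11:30], 8, 10, n_mock = 200,
                   n_pairs = 100, seed = 9)
  expect_identical(n1$draws, n2$draws)
  n3 <- build_null(pool[1:20], pool[11:30], 8, 10, n_mock = 200,
                   n_pairs = 100, seed = 10)
  expect_false(identical(n1$draws, n3$draws))

  # caller's RNG stream is unaffected
  set.seed(1); a <- runif(1)
  set.seed(1)
  invisible(build_null(pool, pool, 5, 5, n_mock = 20, n_pairs = 10, seed = 2))
  expect_identical(runif(1), a)

  # mean/sd recomputable from the stored draws
  expect_equal(n1$mean, mean(n1$draws), tolerance = 1e-12)
  expect_equal(n1$sd, sd(n1$draws), tolerance = 1e-12)

  expect_error(build_null(pool, pool, 40, 5, n_mock = 20, n_pairs = 10),
               "exceeds")
  expect_error(build_null(pool, pool, 5, 5, n_mock = 20, n_pairs = 11),
               "n_mock")
})

test_that("saturated pools give a degenerate null and a missing z", {
  pool <- paste0("A", 1:6)
  nd <- build_null(pool, pool, 6, 6, n_mock = 50, n_pairs = 25, seed = 1)
  expect_true(nd$degenerate)
  expect_true(all(nd$draws == 0))
  res <- beta_zscore(0.4, nd)
  expect_true(is.na(res$z))
  expect_equal(res$reason, "degenerate_null")
})

test_that("null mean and sd converge to the exhaustive expectation on tiny pools", {
  # oracle: enumerate all subset pairs of a 5-ASV pool at richness (2, 3)
  subsets_a <- combn(5, 2, simplify = FALSE)
  subsets_b <- combn(5, 3, simplify = FALSE)
  js <- unlist(lapply(subsets_a, function(a) {
    vapply(subsets_b, function(b) {
      i <- length(intersect(a, b))
      1 - i / (5 - i)
    }, numeric(1))
  }))
  nd <- build_null(letters[1:5], letters[1:5], 2, 3, n_mock = 8000,
                   n_pairs = 4000, seed = 12)
  expect_equal(nd$mean, mean(js), tolerance = 4 * nd$sd / sqrt(4000) / mean(js))
  expect_equal(nd$sd, sqrt(mean((js - mean(js))^2)), tolerance = 0.05)
})

test_that("z-scores center, scale and flag as defined", {
  nd <- build_null(paste0("A", 1:40), paste0("A", 1:40), 10, 10,
                   n_mock = 2000, n_pairs = 1000, seed = 4)
  expect_equal(beta_zscore(nd$mean, nd)$z, 0)
  at_boundary <- beta_zscore(nd$mean - 1.96 * nd$sd, nd)
  expect_equal(at_boundary$z, -1.96)
  expect_false(at_boundary$significant) # strict inequality at the boundary

  fake <- structure(list(mean = 0.9, sd = 0.05, degenerate = FALSE),
                    class = "null_distribution")
  expect_equal(beta_zscore(0.3, fake)$z, -12)
})

test_that("pattern classification reproduces the four dynamics", {
  expect_equal(classify_pattern(-5, -6, -7)$label, "persistent_convergence")
  expect_equal(classify_pattern(0.09, -1.30, -3.58)$label,
               "progressive_convergence")
  expect_equal(classify_pattern(-0.67, -3.39, -0.32)$label,
               "transient_convergence")
  expect_equal(classify_pattern(-1.25, -1.56, -0.18)$label, "null_like")
  # progressive regardless of the After point
  expect_equal(classify_pattern(0, -9, -9)$label, "progressive_convergence")
  # combinations outside the four narrative cases: null_like + atypical
  odd <- classify_pattern(-5, 0, 0)
  expect_equal(odd$label, "null_like")
  expect_true(odd$atypical)
  # positive z never counts as convergence
  expect_equal(classify_pattern(3, 4, 5)$label, "null_like")
  # missing categories are partial
  prt <- classify_pattern(NA, -5, -5)
  expect_true(prt$partial)
  expect_equal(prt$label, "progressive_convergence")
})

test_that("within-experiment comparisons use the experiment's own null", {
  # two identical consecutive samples: observed 0, z at the minimum
  # attainable; a later divergent sample keeps the experiment pool larger
  # than the pair's richness so the null has variance
  comm <- tibble::tibble(
    experiment = "exp1",
    sample_id = rep(c("a", "b", "c"), each = 8),
    asv_id = c(rep(paste0("t", 1:8), 2), paste0("u", 1:8)),
    count = 5L, day = rep(c(-1L, 3L, 9L), each = 8),
    nucleic_acid = "cDNA")
  res <- within_experiment_beta(comm, n_mock = 400, n_pairs = 200, seed = 1)
  ab <- res[res$sample_a == "a" & res$sample_b == "b", ]
  expect_equal(ab$observed_jaccard, 0)
  expect_lt(ab$z, -1.96)
  expect_equal(ab$z, (0 - ab$null_mean) / ab$null_sd)
  expect_lte(ab$observed_jaccard, min(res$observed_jaccard))

  # single sample: no pairs
  one <- dplyr::filter(comm, sample_id == "a")
  expect_equal(nrow(within_experiment_beta(one, n_mock = 50, n_pairs = 25)), 0)
})

test_that("full-turnover experiments show no within-experiment convergence", {
  zs <- vapply(1:12, function(s) {
    cfg <- sim_config(n_experiments = 1, turnover = 1,
                      transient_fraction = 0, fermenter_loss_prob = 0,
                      hydrogenotroph_boost = 1, shared_pool_fraction = 0,
                      sampling_days = list(c(-1L, 2L, 5L, 9L)),
                      injections = list(0L), refills = list(integer()),
                      seed = s)
    ds <- simulate_dataset(cfg)
    res <- within_experiment_beta(ds$community, n_mock = 600, n_pairs = 300,
                                  seed = s)
    mean(res$z)
  }, numeric(1))
  expect_gte(mean(zs), 0)
})

test_that("the Spearman bias check flags monotone dependence and needs n >= 5", {
  mono <- tibble::tibble(z = 1:6 / 2, day_gap = c(0, 1, 3, 5, 8, 13))
  out <- time_differential_bias_check(mono)
  expect_equal(out$rho, 1)
  expect_lte(out$p_value, 0.05)
  expect_true(out$biased)

  expect_error(time_differential_bias_check(
    tibble::tibble(z = c(1, 2), day_gap = c(1, 2))), "at least 5")

  ties <- tibble::tibble(z = rnorm(6), day_gap = rep(2, 6))
  expect_true(is.na(time_differential_bias_check(ties)$p_value))
})

test_that("per-pair child seeds isolate results from unrelated experiments", {
  mk <- function(n) {
    cfg <- sim_config(n_experiments = n, seed = 5)
    simulate_dataset(cfg)
  }
  ds5 <- mk(5)
  ds6 <- mk(6)
  expect_identical(ds5$community,
                   dplyr::filter(ds6$community, experiment != "exp6"))
  args <- list(n_mock = 300, n_pairs = 150, seed = 5)
  b5 <- do.call(pairwise_beta, c(list(
    ds5$community, assign_timepoints_all(ds5$community, ds5$designs)), args))
  b6 <- do.call(pairwise_beta, c(list(
    ds6$community, assign_timepoints_all(ds6$community, ds6$designs)), args))
  shared_rows <- b6$pair %in% b5$pair
  expect_equal(dplyr::arrange(b6[shared_rows, ], pair, category),
               dplyr::arrange(b5, pair, category))
})

test_that("expected z never increases with the engineered shared fraction", {
  mean_z <- vapply(c(0, 0.3, 0.6), function(f) {
    zs <- vapply(1:20, function(s) {
      cfg <- sim_config(n_experiments = 2, shared_pool_fraction = f,
                        shared_experiments = c("exp1", "exp2"),
                        fermenter_loss_prob = 0, hydrogenotroph_boost = 1,
                        sampling_days = list(c(-1L, 2L, 5L)),
                        injections = list(0L), refills = list(integer()),
                        seed = s)
      ds <- simulate_dataset(cfg)
      asn <- assign_timepoints_all(ds$community, ds$designs)
      b <- pairwise_beta(ds$community, asn, n_mock = 400, n_pairs = 200,
                         seed = s)
      mean(b$z)
    }, numeric(1))
    mean(zs)
  }, numeric(1))
  expect_true(all(diff(mean_z) < 0.2)) # nonincreasing up to simulation noise
  expect_lt(mean_z[3], mean_z[1])      # and clearly decreasing overall
})
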