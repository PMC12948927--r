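test_that("the shipped guild table loads and validates", {
  gt <- default_guild_table()
  expect_setequal(unique(gt$guild),
                  c("fermentation", "sulfate_reduction", "methanogenesis",
                    "wood_ljungdahl"))
  expect_equal(unique(gt$module[gt$guild == "methanogenesis"]), "M00567")
  expect_equal(unique(gt$module[gt$guild == "sulfate_reduction"]), "M00596")
  expect_equal(unique(gt$module[gt$guild == "wood_ljungdahl"]), "M00377")
  expect_equal(unique(gt$module[gt$guild == "fermentation"]), "FERM")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_guild_table(gt, path)
  expect_equal(read_guild_table(path), gt)

  bad <- dplyr::mutate(gt, module = "M00567")
  write_guild_table(bad, path)
  expect_error(read_guild_table(path), "mismatch")
})

test_that("annotation carries genus and guild sets, including gaps", {
  comm <- tibble::tibble(
    experiment = "exp1", sample_id = "s1",
    asv_id = c("A1", "A2", "A3"), count = c(5L, 3L, 2L),
    day = -1L, nucleic_acid = "cDNA")
  tax <- tibble::tibble(asv_id = c("A1", "A2", "A3"),
                        genus = c("Methanothermobacter", "Rectinema",
                                  "UnknownGenus"))
  ann <- annotate_guilds(comm, tax)
  expect_equal(ann$guilds[[match("A1", ann$asv_id)]], "methanogenesis")
  expect_equal(ann$guilds[[match("A2", ann$asv_id)]], "fermentation")
  expect_equal(ann$guilds[[match("A3", ann$asv_id)]], character())

  # missing taxonomy errors with the offending ids
  expect_error(annotate_guilds(comm, tax[1:2, ]), "A3")

  # empty guild table: everything unannotated
  empty <- default_guild_table()[0, ]
  ann0 <- annotate_guilds(comm, tax, empty)
  expect_true(all(lengths(ann0$guilds) == 0))
})

test_that("guild trajectories partition relative abundance", {
  comm <- tibble::tibble(
    experiment = "exp1",
    sample_id = rep(c("s1", "s2"), each = 2),
    asv_id = rep(c("A1", "A2"), 2),
    count = c(10L, 10L, 30L, 10L),
    day = rep(c(-1L, 3L), each = 2), nucleic_acid = "cDNA")
  tax <- tibble::tibble(asv_id = c("A1", "A2"),
                        genus = c("Methanothermobacter", "Rectinema"))
  traj <- guild_trajectory(annotate_guilds(comm, tax))
  d1 <- dplyr::filter(traj, day == -1)
  expect_equal(d1$fraction[d1$guild == "methanogenesis"], 0.5)
  expect_equal(d1$fraction[d1$guild == "fermentation"], 0.5)
  d2 <- dplyr::filter(traj, day == 3)
  expect_equal(d2$fraction[d2$guild == "methanogenesis"], 0.75)

  # single guild: fraction 1 at every day
  solo <- annotate_guilds(dplyr::filter(comm, asv_id == "A1"), tax)
  straj <- guild_trajectory(solo)
  expect_true(all(straj$fraction[straj$guild == "methanogenesis"] == 1))

  # fractions (incl. unannotated) sum to 1 per day for single-guild tables
  sums <- traj |>
    dplyr::group_by(day) |>
    dplyr::summarise(s = sum(fraction))
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("multi-guild genera are dual-counted with full weight", {
  comm <- tibble::tibble(experiment = "e", sample_id = "s1",
                         asv_id = c("A1", "A2"), count = c(6L, 2L),
                         day = 0L, nucleic_acid = "cDNA")
  tax <- tibble::tibble(asv_id = c("A1", "A2"), genus = c("Dual", "Other"))
  gt <- tibble::tibble(
    genus = c("Dual", "Dual"),
    guild = c("fermentation", "sulfate_reduction"),
    module = c("FERM", "M00596"),
    ko_ids = c("K00016", "K11180"))
  traj <- guild_trajectory(annotate_guilds(comm, tax, gt))
  expect_equal(traj$fraction[traj$guild == "fermentation"], 0.75)
  expect_equal(traj$fraction[traj$guild == "sulfate_reduction"], 0.75)
  expect_equal(traj$fraction[traj$guild == "unannotated"], 0.25)
})

test_that("hydrogenotroph enrichment raises the H2-fed guild fraction", {
  grew <- vapply(1:40, function(s) {
    cfg <- sim_config(n_experiments = 1, hydrogenotroph_boost = 10,
                      seed = s)
    ds <- simulate_dataset(cfg)
    ann <- annotate_guilds(ds$community, ds$taxonomy, ds$guilds)
    traj <- guild_trajectory(ann) |>
      dplyr::filter(guild %in% c("methanogenesis", "sulfate_reduction")) |>
      dplyr::group_by(day) |>
      dplyr::summarise(f = sum(fraction))
    asn <- assign_timepoints_all(ds$community, ds$designs)
    before <- traj$f[traj$day == asn$day[asn$category == "Before"]]
    furthest <- traj$f[traj$day == asn$day[asn$category == "Furthest"]]
    furthest > before
  }, logical(1))
  expect_gte(mean(grew), 0.9)
})

test_that("core communities are intersections, anti-monotone in scope", {
  fx <- core_fixture()
  core <- core_community(fx$community, fx$assignments, "Furthest")
  expect_setequal(core$asv_id, fx$shared)

  # single-experiment scope: the full presence set of that sample
  solo <- core_community(fx$community, fx$assignments, "Before",
                         scope = "exp1")
  expect_setequal(solo$asv_id,
                  fx$community$asv_id[fx$community$sample_id == "exp1_d-1"])

  # enlarging the scope can only shrink the core
  core12 <- core_community(fx$community, fx$assignments, "After",
                           scope = c("exp1", "exp2"))
  core123 <- core_community(fx$community, fx$assignments, "After",
                            scope = c("exp1", "exp2", "exp3"))
  expect_true(all(core123$asv_id %in% core12$asv_id))

  # disjoint experiments: empty core
  disjoint <- dplyr::mutate(
    fx$community, asv_id = paste0(experiment, "_", asv_id))
  expect_equal(nrow(core_community(disjoint, fx$assignments, "Before")), 0)

  # category missing for an experiment in scope errors
  no_before <- dplyr::filter(fx$assignments,
                             !(experiment == "exp2" & category == "Before"))
  expect_error(core_community(fx$community, no_before, "Before"), "exp2")
})

test_that("chord edges fan out per KO with shared weights", {
  tax <- tibble::tibble(asv_id = c("A1", "A2"),
                        genus = c("GenM", "GenF"))
  gt <- tibble::tibble(
    genus = c("GenM", "GenF"),
    guild = c("methanogenesis", "fermentation"),
    module = c("M00567", "FERM"),
    ko_ids = c("K1;K2;K3", "K4;K5"))
  comm <- tibble::tibble(
    experiment = "e",
    sample_id = rep(c("s1", "s2"), each = 2),
    asv_id = rep(c("A1", "A2"), 2),
    count = c(3L, 1L, 2L, 2L),
    day = rep(c(-1L, 2L), each = 2), nucleic_acid = "cDNA")
  edges <- chord_edges(annotate_guilds(comm, tax, gt), gt)
  # (3 KOs + 2 KOs) x 2 days, all ASVs present
  expect_equal(nrow(edges), 10)
  # per-ASV per-day weights equal across KOs (fan-out, not split)
  spread <- edges |>
    dplyr::group_by(asv_id, day) |>
    dplyr::summarise(w = dplyr::n_distinct(weight), .groups = "drop")
  expect_true(all(spread$w == 1))
  expect_equal(unique(edges$weight[edges$asv_id == "A1" & edges$day == -1]),
               0.75)
  expect_true(all(edges$weight >= 0 & edges$weight <= 1))
  expect_equal(sort(unique(edges$timepoint_index)), c(1, 2))

  # minimal graph: 1 ASV, 1 KO, 1 day
  g1 <- tibble::tibble(genus = "GenM", guild = "methanogenesis",
                       module = "M00567", ko_ids = "K1")
  e1 <- chord_edges(
    annotate_guilds(dplyr::filter(comm, sample_id == "s1", asv_id == "A1"),
                    tax, g1), g1)
  expect_equal(nrow(e1), 1)
  expect_equal(e1$weight, 1)

  # an ASV absent at a day contributes no edge that day
  absent <- dplyr::filter(comm, !(sample_id == "s2" & asv_id == "A1"))
  e2 <- chord_edges(annotate_guilds(absent, tax, gt), gt)
  expect_equal(nrow(dplyr::filter(e2, asv_id == "A1", day == 2)), 0)
})
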