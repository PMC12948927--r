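# Small in-code fixtures shared across test files.

toy_counts <- function() {
  tibble::tibble(
    asv_id = c("ASV_a", "ASV_b", "ASV_c"),
    s1 = c(4L, 0L, 1L),
    s2 = c(1L, 1L, 0L),
    s3 = c(0L, 0L, 1L))
}

toy_metadata <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    experiment = "exp1",
    day = c(-1L, 3L, 8L),
    nucleic_acid = "cDNA")
}

toy_community <- function() {
  as_community(toy_counts(), toy_metadata())
}

# hand-built 3-experiment community sharing an engineered 5-ASV core,
# one sample per (experiment, category)
core_fixture <- function() {
  shared <- paste0("S", 1:5)
  rows <- purrr::map_dfr(1:3, function(e) {
    purrr::map_dfr(c(Before = -1L, After = 1L, Furthest = 4L), function(d) {
      asvs <- c(shared, paste0("P", e, "_", d, "_", 1:4))
      tibble::tibble(experiment = paste0("exp", e),
                     sample_id = paste0("exp", e, "_d", d),
                     asv_id = asvs, count = 10L, day = d,
                     nucleic_acid = "cDNA")
    })
  })
  designs <- tibble::tibble(
    experiment = paste0("exp", 1:3),
    injection_days = list(0L, 0L, 0L),
    refill_days = list(integer(), integer(), integer()),
    sampling_days = list(c(-1L, 1L, 4L), c(-1L, 1L, 4L), c(-1L, 1L, 4L)))
  list(community = rows, designs = designs,
       assignments = assign_timepoints_all(rows, designs),
       shared = shared)
}

# independent Jaccard oracle on logical membership vectors
jaccard_oracle <- function(universe, a, b) {
  va <- universe %in% a
  vb <- universe %in% b
  1 - sum(va & vb) / sum(va | vb)
}
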