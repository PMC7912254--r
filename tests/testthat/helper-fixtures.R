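# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A compact synthetic study reused by several module tests.
small_study <- function() {
  cached("small_study", function() {
    simulate_study(study_config(n_samples = 60, n_taxa = 80,
                                depth_range = c(3000L, 6000L), seed = 42L))
  })
}

small_rarefied <- function() {
  cached("small_rarefied", function() rarefy(small_study()$table, 3000, seed = 42L))
}

tiny_feature_table <- function() {
  counts <- matrix(c(5, 0, 3,
                     2, 4, 0), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("tA", "tB", "tC")))
  lineage <- tibble::tibble(
    taxon_id = c("tA", "tB", "tC"),
    phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes"),
    genus = c("g1", "g2", "g3")
  )
  feature_table(counts, lineage)
}
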