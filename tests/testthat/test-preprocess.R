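test_that("rarefaction conserves depth, drops shallow samples, keeps full-depth rows", {
  counts <- rbind(s1 = c(600, 400), s2 = c(50, 50), s3 = c(80, 20))
  colnames(counts) <- c("tA", "tB")
  ft <- feature_table(counts)
  out <- rarefy(ft, depth = 100, seed = 1)
  expect_true(all(rowSums(out$counts) == 100))
  # a sample whose total equals the depth is returned unchanged
  expect_equal(out$counts["s2", ], counts["s2", ])
  expect_equal(attr(out, "dropped"), character(0))
  expect_message(out2 <- rarefy(ft, depth = 150, seed = 1), "dropped 2")
  expect_equal(rownames(out2$counts), "s1")
  expect_true(all(rowSums(out2$counts) == 150))
  expect_error(rarefy(ft, depth = 0), "depth")
})

test_that("rarefaction is a seeded hypergeometric draw with unbiased proportions", {
  counts <- matrix(c(1e6, 1e6), 1, dimnames = list("s1", c("tA", "tB")))
  ft <- feature_table(counts)
  props <- vapply(1:100, function(s) {
    rarefy(ft, depth = 1e4, seed = s)$counts[1, "tA"] / 1e4
  }, numeric(1))
  n <- 1e4; N <- 2e6
  hyper_sd <- sqrt(n * 0.5 * 0.5 * (N - n) / (N - 1)) / n
  expect_lt(abs(mean(props) - 0.5), 3 * hyper_sd / sqrt(100))
  expect_identical(rarefy(ft, 1e4, seed = 7)$counts, rarefy(ft, 1e4, seed = 7)$counts)
})

test_that("rarefaction expectation preserves composition", {
  counts <- matrix(c(500, 300, 150, 50), 1, dimnames = list("s1", paste0("t", 1:4)))
  ft <- feature_table(counts)
  depth <- 200
  draws <- t(vapply(1:200, function(s) rarefy(ft, depth, seed = s)$counts[1, ] / depth,
                    numeric(4)))
  p <- counts[1, ] / sum(counts)
  se <- sqrt(p * (1 - p) / depth) / sqrt(200)
  expect_true(all(abs(colMeans(draws) - p) < 3 * pmax(se, 1e-6)))
})

test_that("taxonomic aggregation sums by rank and conserves totals", {
  counts <- matrix(c(1, 2, 4), 1, dimnames = list("s1", c("g1", "g2", "g3")))
  lineage <- tibble::tibble(taxon_id = c("g1", "g2", "g3"),
                            phylum = c("p1", "p1", "p2"),
                            genus = c("g1", "g2", "g3"))
  ft <- feature_table(counts, lineage)
  agg <- aggregate_taxa(ft, "phylum")
  expect_equal(agg$counts[1, c("p1", "p2")], c(p1 = 3, p2 = 4))

  rare <- small_rarefied()
  for (rank in c("phylum", "genus")) {
    agg <- aggregate_taxa(rare, rank)
    expect_equal(rowSums(agg$counts), rowSums(rare$counts))
  }
  one <- aggregate_taxa(feature_table(counts, dplyr::mutate(lineage, phylum = "p1")),
                        "phylum")
  expect_equal(ncol(one$counts), 1)
  expect_equal(as.numeric(one$counts), 7)
  expect_error(aggregate_taxa(rare, "kingdom"), "unknown rank")
})

test_that("proportions normalise rows and are scale invariant", {
  counts <- matrix(c(1, 1, 2, 10, 10, 20), 2, byrow = TRUE,
                   dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
  cm <- to_proportions(feature_table(counts))
  expect_equal(cm$values["a", ], c(t1 = 0.25, t2 = 0.25, t3 = 0.5))
  expect_equal(cm$values["a", ], cm$values["b", ])
  expect_equal(unname(rowSums(cm$values)), c(1, 1))
  zero <- matrix(c(1, 0, 0, 0), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_error(to_proportions(feature_table(zero)), "degenerate-input.*b")
})

test_that("Bayesian-multiplicative zero replacement matches its closed form", {
  vals <- matrix(c(0, 0.4, 0.6), 1, dimnames = list("s1", c("t1", "t2", "t3")))
  cm <- composition(vals, "proportions", totals = c(s1 = 100))
  out <- replace_zeros(cm, prior_strength = 0.5)
  delta <- 0.5 / (100 + 1.5)
  expect_equal(out$values[1, "t1"], delta, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(out$values[1, "t2"], 0.4 * (1 - delta), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(out$values), 1, tolerance = 1e-12)
  # ratios of non-zero parts preserved exactly
  expect_equal(out$values[1, "t2"] / out$values[1, "t3"], 0.4 / 0.6, tolerance = 1e-12)
  # rows without zeros pass through identically
  full <- composition(matrix(c(0.2, 0.8), 1, dimnames = list("s1", c("t1", "t2"))),
                      "proportions", totals = c(s1 = 50))
  expect_identical(replace_zeros(full)$values, full$values)
})

test_that("clr centres log abundances and requires positive input", {
  vals <- matrix(c(1, 2, 4) / 7, 1, dimnames = list("s1", c("t1", "t2", "t3")))
  cm <- composition(vals, "zero_replaced", totals = c(s1 = 7))
  out <- clr_transform(cm)
  expect_equal(unname(out$values[1, ]), c(-log(2), 0, log(2)), tolerance = 1e-12)
  uni <- composition(matrix(rep(0.25, 4), 1, dimnames = list("s1", paste0("t", 1:4))),
                     "zero_replaced", totals = c(s1 = 4))
  expect_equal(unname(clr_transform(uni)$values[1, ]), rep(0, 4))
  withz <- composition(matrix(c(0, 0.5, 0.5), 1, dimnames = list("s1", paste0("t", 1:3))),
                       "proportions", totals = c(s1 = 10))
  expect_error(clr_transform(withz), "replace_zeros")
})

test_that("clr after zero replacement is invariant to count scale on zero-free samples", {
  set.seed(4)
  counts <- matrix(rpois(40, 30) + 1, 4, dimnames = list(paste0("s", 1:4), paste0("t", 1:10)))
  cm1 <- clr_transform(replace_zeros(to_proportions(feature_table(counts))))
  cm2 <- clr_transform(replace_zeros(to_proportions(feature_table(counts * 13))))
  expect_equal(cm1$values, cm2$values, tolerance = 1e-10)
})

test_that("clr log-ratio equals the direct log proportion ratio", {
  rare <- small_rarefied()
  agg <- aggregate_taxa(rare, "phylum")
  props <- to_proportions(agg)
  cm <- clr_transform(replace_zeros(props))
  fb <- clr_log_ratio(cm, "Firmicutes", "Bacteroidetes")
  zr <- replace_zeros(props)
  direct <- log(zr$values[, "Firmicutes"] / zr$values[, "Bacteroidetes"])
  expect_equal(fb, direct, tolerance = 1e-12)
  expect_equal(fb, -clr_log_ratio(cm, "Bacteroidetes", "Firmicutes"), tolerance = 1e-12)
  expect_error(clr_log_ratio(cm, "Firmicutes", "NotAPhylum"), "missing part")
})

test_that("energy adjustment removes energy structure and nothing else", {
  set.seed(2)
  n <- 400
  energy <- exp(rnorm(n, log(2000), 0.25))
  # intake exactly proportional to energy collapses to a constant
  diet <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                         total_energy = energy, propfood = 0.1 * energy)
  adj <- adjust_diet(diet)
  expect_lt(sd(adj$propfood), 1e-10)
  # independent intake is returned almost unchanged (up to location)
  cors <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    indep <- exp(rnorm(n, log(50), 0.5))
    d <- tibble::tibble(sample_id = diet$sample_id, total_energy = energy,
                        food = indep)
    a <- adjust_diet(d)
    cor(a$food, log(indep))
  }, numeric(1))
  expect_gt(mean(cors), 0.99)
  # OLS orthogonality: adjusted columns uncorrelated with log energy
  st <- small_study()
  adj2 <- adjust_diet(st$diet)
  foods <- setdiff(names(adj2), "sample_id")
  max_r <- max(abs(vapply(foods, function(f) cor(adj2[[f]], log(st$diet$total_energy)),
                          numeric(1))))
  expect_lt(max_r, 1e-8)
  const <- tibble::tibble(sample_id = c("a", "b"), total_energy = c(2000, 2000),
                          food = c(1, 2))
  expect_error(adjust_diet(const), "degenerate-design")
})

test_that("zero intakes receive the half-minimum offset before logging", {
  diet <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                         total_energy = c(1800, 2000, 2200, 2400),
                         food = c(0, 2, 4, 8))
  expect_silent(adj <- adjust_diet(diet))
  expect_true(all(is.finite(adj$food)))
})
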