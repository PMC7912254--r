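test_that("chao1 matches its bias-corrected closed form", {
  expect_equal(chao1(c(2, 2, 2)), 3)               # no singletons
  expect_equal(chao1(c(1, 1, 2, 4)), 4.5)          # F1=2, F2=1
  expect_equal(chao1(c(5, 3, 1, 1)), 5.0)          # F1=2, F2=0
  x <- c(3, 0, 1, 1, 1, 2, 2, 7)
  expect_gte(chao1(x), sum(x > 0))
  expect_error(chao1(c(0, 0)), "degenerate-input")
})

test_that("shannon matches closed forms across bases", {
  expect_equal(shannon(c(0, 7, 0)), 0)
  expect_equal(shannon(rep(1, 4)), log(4))
  expect_equal(shannon(c(1, 1, 2)), -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)),
               tolerance = 1e-12)
  for (S in 2:64) expect_equal(shannon(rep(3, S)), log(S), tolerance = 1e-12)
  expect_equal(shannon(rep(1, 4), base = 2), 2)
  expect_error(shannon(numeric(3)), "degenerate-input")
})

test_that("faith PD sums the spanning branch lengths", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1):0;")
  expect_equal(faith_pd(c(A = 1, B = 2, C = 3), star), 3)
  expect_equal(faith_pd(c(A = 1, B = 0, C = 0), star), 1)
  cat <- ape::read.tree(text = "((A:1,B:1):1,C:2):0;")
  expect_equal(faith_pd(c(A = 1, B = 0, C = 5), cat), 4)
  expect_error(faith_pd(c(A = 1, Z = 1), star), "invalid-argument.*Z")
})

test_that("faith PD agrees with picante on random instances", {
  skip_if_not_installed("picante")
  set.seed(10)
  tr <- random_rooted_tree(30)
  mat <- t(replicate(12, random_counts_row(tr$tip.label)))
  rownames(mat) <- paste0("s", 1:12)
  mine <- faith_pd(mat, tr)
  ref <- picante::pd(mat, tr, include.root = TRUE)$PD
  expect_equal(unname(mine), ref, tolerance = 1e-10)
})

test_that("bray-curtis reproduces hand values and stays in [0,1]", {
  m <- rbind(a = c(0.75, 0.25), b = c(0.25, 0.75), c = c(0.75, 0.25),
             d = c(1, 0), e = c(0, 1))
  colnames(m) <- c("t1", "t2")
  d <- bray_curtis(m)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["d", "e"], 1)
  expect_equal(d["a", "b"], 0.5)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("unifrac matches the brute-force branch enumeration oracle", {
  set.seed(11)
  for (n_tips in 2:6) {
    for (rep in 1:4) {
      tr <- random_rooted_tree(n_tips)
      mat <- t(replicate(6, random_counts_row(tr$tip.label)))
      rownames(mat) <- paste0("s", 1:6)
      du <- unweighted_unifrac(mat, tr)
      dw <- weighted_unifrac(mat, tr)
      dwn <- weighted_unifrac(mat, tr, normalized = TRUE)
      for (i in 1:5) for (j in (i + 1):6) {
        expect_equal(du[i, j], brute_unifrac(tr, mat[i, ], mat[j, ]), tolerance = 1e-10)
        expect_equal(dw[i, j], brute_unifrac(tr, mat[i, ], mat[j, ], weighted = TRUE),
                     tolerance = 1e-10)
        expect_equal(dwn[i, j],
                     brute_unifrac(tr, mat[i, ], mat[j, ], weighted = TRUE, normalized = TRUE),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("unifrac limit cases: identical samples and disjoint root clades", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1):0;")
  m <- rbind(s1 = c(A = 3, B = 1, C = 0, D = 0),
             s2 = c(A = 3, B = 1, C = 0, D = 0),
             s3 = c(A = 0, B = 0, C = 2, D = 5))
  du <- unweighted_unifrac(m, tr)
  expect_equal(du["s1", "s2"], 0)
  expect_equal(du["s1", "s3"], 1)  # no shared branches
  dw <- weighted_unifrac(m, tr, normalized = TRUE)
  expect_equal(dw["s1", "s2"], 0)
  expect_equal(dw["s1", "s3"], 1)
  # 3-leaf star, unit lengths, (1,0,0) vs (0,1,0): raw distance 1+1 = 2
  star <- ape::read.tree(text = "(A:1,B:1,C:1):0;")
  m2 <- rbind(x = c(A = 1, B = 0, C = 0), y = c(A = 0, B = 1, C = 0))
  expect_equal(weighted_unifrac(m2, star)["x", "y"], 2)
})

test_that("unifrac agrees with phyloseq on a larger random instance", {
  skip_if_not_installed("phyloseq")
  set.seed(12)
  tr <- random_rooted_tree(40)
  mat <- t(replicate(15, random_counts_row(tr$tip.label)))
  rownames(mat) <- paste0("s", 1:15)
  ps <- phyloseq::phyloseq(phyloseq::otu_table(mat, taxa_are_rows = FALSE),
                           phyloseq::phy_tree(tr))
  expect_equal(unweighted_unifrac(mat, tr),
               as.matrix(phyloseq::UniFrac(ps, weighted = FALSE)), tolerance = 1e-8)
  expect_equal(weighted_unifrac(mat, tr, normalized = TRUE),
               as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE)),
               tolerance = 1e-8)
})

test_that("distances satisfy metric axioms on random instances", {
  set.seed(13)
  tr <- random_rooted_tree(12)
  mat <- t(replicate(10, random_counts_row(tr$tip.label)))
  rownames(mat) <- paste0("s", 1:10)
  for (d in list(bray_curtis(mat / rowSums(mat)),
                 unweighted_unifrac(mat, tr),
                 weighted_unifrac(mat, tr, normalized = TRUE))) {
    expect_equal(d, t(d), tolerance = 1e-12)
    expect_equal(unname(diag(d)), rep(0, 10))
    expect_true(all(d >= 0))
  }
  # triangle inequality for the two bounded metrics on 100 random triples
  du <- unweighted_unifrac(mat, tr)
  db <- bray_curtis(mat / rowSums(mat))
  for (rep in 1:100) {
    ijk <- sample(10, 3)
    for (d in list(du, db)) {
      expect_lte(d[ijk[1], ijk[2]],
                 d[ijk[1], ijk[3]] + d[ijk[3], ijk[2]] + 1e-12)
    }
  }
})

test_that("taxon column order never changes a diversity result", {
  set.seed(14)
  tr <- random_rooted_tree(15)
  mat <- t(replicate(8, random_counts_row(tr$tip.label)))
  rownames(mat) <- paste0("s", 1:8)
  perm <- sample(ncol(mat))
  mp <- mat[, perm]
  expect_equal(apply(mat, 1, chao1), apply(mp, 1, chao1))
  expect_equal(apply(mat, 1, shannon), apply(mp, 1, shannon))
  expect_equal(faith_pd(mat, tr), faith_pd(mp, tr))
  expect_equal(weighted_unifrac(mat, tr), weighted_unifrac(mp, tr), tolerance = 1e-12)
  expect_equal(unweighted_unifrac(mat, tr), unweighted_unifrac(mp, tr), tolerance = 1e-12)
})

test_that("alpha_diversity assembles all indices with bounds respected", {
  st <- small_study()
  rare <- small_rarefied()
  al <- alpha_diversity(rare, st$tree)
  expect_named(al, c("sample_id", "observed", "chao1", "shannon", "faith_pd"))
  expect_true(all(al$chao1 >= al$observed))
  expect_true(all(al$shannon >= 0 & al$shannon <= log(ncol(rare$counts))))
  total_bl <- sum(st$tree$edge.length)
  expect_true(all(al$faith_pd <= total_bl))
})

test_that("beta_diversity dispatches and requires a tree for unifrac", {
  rare <- small_rarefied()
  expect_error(beta_diversity(rare, "weighted_unifrac"), "tree")
  d <- beta_diversity(rare, "bray_curtis")
  expect_equal(dim(d), c(60, 60))
})
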