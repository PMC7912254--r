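test_that("pcoa reproduces euclidean configurations exactly", {
  # 3 collinear points: a 1-D configuration
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  res <- suppressWarnings(pcoa(d, n_axes = 2))
  rec <- as.matrix(dist(res$coordinates[, 1]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-10)
  expect_lt(res$eigenvalues[2], 1e-10)

  set.seed(41)
  pts <- matrix(rnorm(40), 20, 2)
  rownames(pts) <- sprintf("s%02d", 1:20)
  dm <- as.matrix(dist(pts))
  res2 <- pcoa(dm, n_axes = 2)
  expect_equal(as.matrix(dist(res2$coordinates)), dm, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unname(colMeans(res2$coordinates)), c(0, 0), tolerance = 1e-8)
  expect_equal(res2$negative_eigenvalue_mass, 0, tolerance = 1e-8)
  expect_warning(pcoa(d, n_axes = 3), "truncating")
})

test_that("non-euclidean dissimilarities report their negative eigenvalue mass", {
  rare <- small_rarefied()
  d <- bray_curtis(to_proportions(rare))
  res <- pcoa(d)
  expect_gt(res$negative_eigenvalue_mass, 0)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
})

test_that("kmeans recovers planted blobs and is deterministic", {
  set.seed(42)
  blobs <- rbind(cbind(rnorm(30, 0), rnorm(30, 0)),
                 cbind(rnorm(30, 8), rnorm(30, 0)),
                 cbind(rnorm(30, 0), rnorm(30, 16)))
  rownames(blobs) <- sprintf("s%03d", 1:90)
  truth <- rep(1:3, each = 30)
  lab <- kmeans_cluster(blobs, 3, seed = 5)
  expect_equal(mclust::adjustedRandIndex(lab, truth), 1)
  expect_identical(as.integer(lab), as.integer(kmeans_cluster(blobs, 3, seed = 5)))
  one <- kmeans_cluster(blobs, 1, seed = 5)
  expect_equal(attr(one, "centers")[1, ], colMeans(blobs), ignore_attr = TRUE)
  expect_error(kmeans_cluster(blobs, 100, seed = 1), "k <= n")
})

test_that("wss decreases in k and choose_k flags planted structure", {
  set.seed(43)
  blobs <- rbind(cbind(rnorm(40, 0), rnorm(40, 0)),
                 cbind(rnorm(40, 6), rnorm(40, 0)),
                 cbind(rnorm(40, 0), rnorm(40, 12)))
  diag <- choose_k(blobs, k_max = 6, B = 20, seed = 2)
  expect_true(all(diff(diag$wss) <= 1e-9))
  sug <- attr(diag, "suggested")
  expect_equal(unname(sug["silhouette"]), 3)
  expect_equal(unname(sug["gap"]), 3)
  expect_error(choose_k(blobs, B = 1), "B")
})

test_that("gap statistic prefers k = 1 for structureless data", {
  hits <- vapply(1:10, function(s) {
    set.seed(400 + s)
    x <- matrix(runif(160), 80, 2)
    sug <- attr(choose_k(x, k_max = 5, B = 25, seed = s), "suggested")
    sug["gap"] == 1
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("enterotype labelling uses the differential-mean rule injectively", {
  props <- rbind(
    s1 = c(0.7, 0.2, 0.1), s2 = c(0.6, 0.3, 0.1),   # cluster 1: gA dominant
    s3 = c(0.5, 0.4, 0.1), s4 = c(0.45, 0.45, 0.1), # cluster 2: gB differential
    s5 = c(0.2, 0.2, 0.6), s6 = c(0.25, 0.15, 0.6)  # cluster 3: gC dominant
  )
  colnames(props) <- c("gA", "gB", "gC")
  labels <- setNames(c(1L, 1L, 2L, 2L, 3L, 3L), rownames(props))
  lab <- label_enterotypes(labels, props)
  expect_equal(unname(lab[c("1", "2", "3")]), c("gA", "gB", "gC"))
  # k = 1 degenerates to the overall-mean maximiser
  lab1 <- label_enterotypes(setNames(rep(1L, 6), rownames(props)), props)
  expect_equal(unname(lab1), "gA")
  # sample order invariance
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(label_enterotypes(labels[perm], props[perm, ]), lab)
  # injectivity: clusters cannot share a genus
  two <- rbind(s1 = c(0.8, 0.2), s2 = c(0.8, 0.2), s3 = c(0.7, 0.3), s4 = c(0.7, 0.3))
  colnames(two) <- c("gX", "gY")
  lab2 <- label_enterotypes(setNames(c(1L, 1L, 2L, 2L), rownames(two)), two)
  expect_setequal(unname(lab2), c("gX", "gY"))
})

test_that("planted enterotypes are recovered and named from either distance matrix", {
  st <- small_study()
  rare <- small_rarefied()
  genus <- to_proportions(aggregate_taxa(rare, "genus"))
  truth <- st$truth$enterotype[match(rownames(rare$counts), st$truth$sample_id)]
  fits <- list(
    wuf = find_enterotypes(weighted_unifrac(rare, st$tree), genus, k = 3,
                           seed = 1, diagnostics = FALSE),
    bc = find_enterotypes(bray_curtis(to_proportions(rare)), genus, k = 3,
                          seed = 1, diagnostics = FALSE)
  )
  for (fit in fits) {
    expect_gte(mclust::adjustedRandIndex(fit$labels$cluster, truth), 0.9)
    expect_setequal(fit$dominant_genus, c("Bacteroides", "Prevotella", "Ruminococcus"))
  }
  # stability across metrics, the hallmark of a real enterotype structure
  expect_gte(mclust::adjustedRandIndex(fits$wuf$labels$cluster,
                                       fits$bc$labels$cluster), 0.8)
  td <- tidy(fits$wuf)
  expect_true(all(c("sample_id", "cluster", "enterotype", "PCo1", "PCo2") %in% names(td)))
  expect_equal(nrow(td), 60)
})

test_that("enterotype contrasts reproduce hand-computed group summaries", {
  labels <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                           cluster = c(1L, 1L, 1L, 2L, 2L, 2L))
  vars <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                         v = c(1, 2, 3, 10, 11, 12))
  out <- enterotype_contrasts(labels, vars)
  expect_equal(out$mean, c(2, 11))
  expect_equal(out$q25, c(1.5, 10.5))
  expect_equal(out$q75, c(2.5, 11.5))
  expect_lt(out$p_value[1], 0.01)
})

test_that("a planted group shift in one food is detected by the contrasts", {
  set.seed(44)
  hits <- vapply(1:20, function(s) {
    set.seed(500 + s)
    n <- 90
    labels <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                             cluster = rep(1:3, each = 30))
    vars <- tibble::tibble(sample_id = labels$sample_id,
                           shifted = rnorm(n) + (labels$cluster == 2) * 1.0,
                           null = rnorm(n))
    out <- enterotype_contrasts(labels, vars)
    out$p_value[out$variable == "shifted"][1] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
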