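#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres `-D^2/2` and eigendecomposes (via `stats::cmdscale`);
#' coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues. Negative eigenvalues — which arise for non-Euclidean
#' dissimilarities such as Bray-Curtis — are excluded and their absolute mass
#' reported, with no correction applied.
#'
#' @param dm Distance matrix with sample-id dimnames.
#' @param n_axes Number of axes to retain (default 2); truncated with a
#'   warning if fewer positive eigenvalues exist.
#' @return Object of class `pcoa_result`: `coordinates` (n x m matrix,
#'   columns `PCo1`, ...), `eigenvalues` (all, descending),
#'   `negative_eigenvalue_mass`, `variance_explained` (per retained axis,
#'   fraction of positive-eigenvalue sum).
#' @export
pcoa <- function(dm, n_axes = 2) {
  dm <- as_distance_matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("invalid-argument: need at least 3 samples", call. = FALSE)
  res <- suppressWarnings(stats::cmdscale(dm, k = n - 1, eig = TRUE))
  eig <- sort(res$eig, decreasing = TRUE)
  tol <- max(abs(eig)) * 1e-10
  n_pos <- sum(eig > tol)
  m <- n_axes
  if (m > n_pos) {
    warning("only ", n_pos, " positive eigenvalues; truncating to ", n_pos, " axes")
    m <- n_pos
  }
  coords <- res$points[, seq_len(m), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(m))
  rownames(coords) <- rownames(dm)
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    negative_eigenvalue_mass = sum(abs(eig[eig < 0])),
    variance_explained = eig[seq_len(m)] / sum(eig[eig > 0])
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d samples, %d axes (%.1f%% / %.1f%% variance), neg. eig. mass %.3g\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$variance_explained[1],
              if (ncol(x$coordinates) > 1) 100 * x$variance_explained[2] else 0,
              x$negative_eigenvalue_mass))
  invisible(x)
}

kmpp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1, prob = probs), ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
    }
  }
  centers
}

lloyd <- function(x, centers, iter_max = 100) {
  n <- nrow(x)
  k <- nrow(centers)
  labels_old <- rep(0L, n)
  for (it in seq_len(iter_max)) {
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    labels <- max.col(-d2, ties.method = "first")
    # re-seed any empty cluster with the point farthest from its centre
    for (j in which(tabulate(labels, k) == 0)) {
      far <- which.max(d2[cbind(seq_len(n), labels)])
      labels[far] <- j
      d2[far, ] <- Inf
    }
    if (identical(labels, labels_old)) break
    labels_old <- labels
    for (j in seq_len(k)) centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
  }
  wss <- sum((x - centers[labels, , drop = FALSE])^2)
  list(labels = labels, centers = centers, wss = wss)
}

#' K-means clustering with k-means++ restarts
#'
#' Lloyd iterations from `n_init` k-means++ seedings, keeping the solution
#' with the lowest within-cluster sum of squares. Deterministic given `seed`;
#' empty clusters are resolved by re-seeding the point farthest from its
#' assigned centre.
#'
#' @param coordinates Numeric matrix (e.g. the first two principal
#'   coordinates), rows = samples.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Integer seed.
#' @param n_init Number of restarts (default 50).
#' @return Integer labels in `1..k` (named by the matrix rownames), with
#'   attributes `"wss"` and `"centers"`.
#' @export
kmeans_cluster <- function(coordinates, k, seed = 1L, n_init = 50) {
  x <- as.matrix(coordinates)
  n <- nrow(x)
  if (k < 1 || k > n) stop("invalid-argument: need 1 <= k <= n", call. = FALSE)
  set.seed(substream_seed(seed, "kmeans"))
  best <- NULL
  for (rep in seq_len(n_init)) {
    fit <- lloyd(x, kmpp_init(x, k))
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  out <- stats::setNames(best$labels, rownames(x))
  attr(out, "wss") <- best$wss
  attr(out, "centers") <- best$centers
  out
}

#' Cluster-number diagnostics: elbow, silhouette, gap statistic
#'
#' For `k = 1..k_max`: within-cluster sum of squares (elbow curve), mean
#' silhouette width (from `k = 2`), and the gap statistic
#' `mean_B log W*_kb - log W_k` with `B` uniform reference sets drawn over
#' the bounding box of the coordinates, plus its standard error
#' `sd * sqrt(1 + 1/B)`. Suggested k per criterion: elbow = largest second
#' difference of the WSS curve, silhouette = argmax, gap = smallest k with
#' `gap(k) >= gap(k+1) - se(k+1)`. The final choice of k is the caller's.
#'
#' @param coordinates Numeric matrix, rows = samples.
#' @param k_max Largest k to evaluate (default 8).
#' @param B Number of gap-statistic reference sets (default 50; must be
#'   >= 2).
#' @param seed Integer seed.
#' @param n_init Restarts per k-means run (default 10).
#' @param criteria Criteria to evaluate (subset of
#'   `c("elbow", "silhouette", "gap")`); dropping `"gap"` skips the reference
#'   bootstrap.
#' @return Tibble of class `k_diagnostics`: `k`, `wss`, `silhouette`, `gap`,
#'   `gap_se`; attribute `"suggested"` is a named integer vector
#'   (elbow/silhouette/gap, for the criteria evaluated).
#' @export
choose_k <- function(coordinates, k_max = 8, B = 50, seed = 1L, n_init = 10,
                     criteria = c("elbow", "silhouette", "gap")) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  x <- as.matrix(coordinates)
  if (k_max < 2) stop("invalid-argument: k_max must be >= 2", call. = FALSE)
  if (B < 2) stop("invalid-argument: B must be >= 2", call. = FALSE)
  n <- nrow(x)
  k_max <- min(k_max, n - 1)
  dx <- stats::dist(x)
  wss_of <- function(xx, k, seed) as.numeric(attr(kmeans_cluster(xx, k, seed, n_init), "wss"))
  ks <- seq_len(k_max)
  wss <- numeric(k_max)
  sil <- rep(NA_real_, k_max)
  for (k in ks) {
    labels <- kmeans_cluster(x, k, substream_seed(seed, paste0("k", k)), n_init)
    wss[k] <- attr(labels, "wss")
    if (k >= 2 && "silhouette" %in% criteria) {
      sil[k] <- mean(cluster::silhouette(as.integer(labels), dx)[, "sil_width"])
    }
  }
  gap <- gap_se <- rep(NA_real_, k_max)
  if ("gap" %in% criteria) {
    # gap statistic: uniform reference over the coordinate bounding box
    set.seed(substream_seed(seed, "gap"))
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
    log_wstar <- matrix(NA_real_, B, k_max)
    for (b in seq_len(B)) {
      ref <- sapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]))
      ref_seed <- substream_seed(seed, paste0("gapref", b))
      for (k in ks) log_wstar[b, k] <- log(wss_of(ref, k, ref_seed))
    }
    gap <- colMeans(log_wstar) - log(wss)
    gap_se <- apply(log_wstar, 2, stats::sd) * sqrt(1 + 1 / B)
  }
  elbow_k <- if (k_max >= 3) {
    d2 <- wss[1:(k_max - 2)] - 2 * wss[2:(k_max - 1)] + wss[3:k_max]
    which.max(d2) + 1L
  } else 2L
  sil_k <- if (all(is.na(sil))) NA_integer_ else which.max(sil)
  gap_k <- NA_integer_
  if ("gap" %in% criteria) {
    gap_k <- k_max
    for (k in seq_len(k_max - 1)) {
      if (gap[k] >= gap[k + 1] - gap_se[k + 1]) { gap_k <- k; break }
    }
  }
  out <- tibble::tibble(k = ks, wss = wss, silhouette = sil, gap = gap,
                        gap_se = gap_se)
  attr(out, "suggested") <- c(elbow = as.integer(elbow_k),
                              silhouette = as.integer(sil_k),
                              gap = as.integer(gap_k))
  class(out) <- c("k_diagnostics", class(out))
  out
}

#' Name clusters by their most discriminating genus
#'
#' Each cluster is named by the genus maximising (mean proportion within the
#' cluster - mean proportion in all other clusters); with a single cluster
#' the overall mean is used. Ties break by within-cluster mean, then
#' lexicographically. The mapping is injective: when two clusters select the
#' same genus, the lower-scoring cluster takes its next-best genus.
#'
#' @param labels Integer cluster labels (named by sample id or aligned to
#'   `genus_proportions` rows).
#' @param genus_proportions A [composition()] of genus-level proportions (or
#'   a row-normalised matrix).
#' @return Named character vector: cluster id -> genus.
#' @export
label_enterotypes <- function(labels, genus_proportions) {
  vals <- if (inherits(genus_proportions, "composition")) genus_proportions$values
          else as.matrix(genus_proportions)
  if (!is.null(names(labels)) && !is.null(rownames(vals))) {
    labels <- labels[rownames(vals)]
  }
  stopifnot(length(labels) == nrow(vals))
  ks <- sort(unique(as.integer(labels)))
  genera <- colnames(vals)
  within <- t(sapply(ks, function(k) colMeans(vals[labels == k, , drop = FALSE])))
  score <- if (length(ks) == 1) within else {
    t(sapply(seq_along(ks), function(i) {
      others <- colMeans(vals[labels != ks[i], , drop = FALSE])
      within[i, ] - others
    }))
  }
  rownames(score) <- rownames(within) <- ks
  assignment <- stats::setNames(rep(NA_character_, length(ks)), ks)
  taken <- character()
  remaining <- as.character(ks)
  while (length(remaining) > 0) {
    # greedy: best available (cluster, genus) pair by differential score,
    # ties by within-cluster mean then genus name
    cand <- do.call(rbind, lapply(remaining, function(k) {
      avail <- setdiff(genera, taken)
      ord <- order(-score[k, avail], -within[k, avail], avail)
      data.frame(cluster = k, genus = avail[ord[1]],
                 score = score[k, avail[ord[1]]],
                 within = within[k, avail[ord[1]]],
                 stringsAsFactors = FALSE)
    }))
    cand <- cand[order(-cand$score, -cand$within, cand$genus), ]
    pick <- cand[1, ]
    assignment[pick$cluster] <- pick$genus
    taken <- c(taken, pick$genus)
    remaining <- setdiff(remaining, pick$cluster)
  }
  assignment
}

#' Discover enterotypes from a beta-diversity matrix
#'
#' PCoA on the distance matrix, k-means on the first `n_axes` principal
#' coordinates, k-selection diagnostics over `1..k_max`, and dominant-genus
#' labelling.
#'
#' @param dm Distance matrix.
#' @param genus_proportions Genus-level [composition()] used for labelling
#'   (optional; clusters stay numbered without it).
#' @param k Number of clusters (default 3; the diagnostics inform but do not
#'   override this choice).
#' @param n_axes Principal coordinates used for clustering (default 2).
#' @param k_max,B Passed to [choose_k()]; set `diagnostics = FALSE` to skip.
#' @param seed Integer seed.
#' @param diagnostics Compute [choose_k()] diagnostics (default TRUE).
#' @return Object of class `enterotype_fit`: `labels` (tibble: `sample_id`,
#'   `cluster`, `enterotype`), `k`, `dominant_genus`, `pcoa`, `diagnostics`.
#' @export
find_enterotypes <- function(dm, genus_proportions = NULL, k = 3, n_axes = 2,
                             k_max = 8, B = 50, seed = 1L, diagnostics = TRUE) {
  pc <- pcoa(dm, n_axes = n_axes)
  labels <- kmeans_cluster(pc$coordinates, k, seed = seed)
  diag_tbl <- if (diagnostics) choose_k(pc$coordinates, k_max = k_max, B = B, seed = seed)
              else NULL
  dominant <- if (!is.null(genus_proportions)) {
    label_enterotypes(labels, genus_proportions)
  }
  lab_tbl <- tibble::tibble(sample_id = rownames(pc$coordinates),
                            cluster = as.integer(labels))
  if (!is.null(dominant)) lab_tbl$enterotype <- unname(dominant[as.character(lab_tbl$cluster)])
  structure(list(labels = lab_tbl, k = k, dominant_genus = dominant,
                 pcoa = pc, diagnostics = diag_tbl),
            class = "enterotype_fit")
}

#' @export
print.enterotype_fit <- function(x, ...) {
  sizes <- table(x$labels$cluster)
  cat(sprintf("<enterotype_fit> k = %d (sizes %s)%s\n", x$k,
              paste(sizes, collapse = "/"),
              if (!is.null(x$dominant_genus))
                paste0("; dominant genera: ", paste(x$dominant_genus, collapse = ", "))
              else ""))
  invisible(x)
}

#' Broom-style accessors for an enterotype fit
#'
#' `tidy()` returns one row per sample with cluster label and PCo
#' coordinates; `glance()` the one-row solution summary.
#'
#' @param x An `enterotype_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.enterotype_fit <- function(x, ...) {
  dplyr::bind_cols(x$labels, tibble::as_tibble(x$pcoa$coordinates))
}

#' @rdname tidy.enterotype_fit
#' @export
glance.enterotype_fit <- function(x, ...) {
  sil <- if (!is.null(x$diagnostics)) x$diagnostics$silhouette[x$k] else NA_real_
  tibble::tibble(k = x$k, n = nrow(x$labels), silhouette = sil,
                 negative_eigenvalue_mass = x$pcoa$negative_eigenvalue_mass)
}

#' Covariate-adjusted enterotype contrasts
#'
#' For each variable (dietary-pattern score, adjusted food-group intakes,
#' macronutrients): the covariate-adjusted group F test across enterotypes
#' plus per-group means and interquartile ranges.
#'
#' @param fit An [find_enterotypes()] result (or a labels tibble with
#'   `sample_id`, `cluster`).
#' @param variables Tibble with `sample_id` and numeric columns to contrast.
#' @param covariates Optional covariate tibble with `sample_id`.
#' @return Long tibble: `variable`, `group`, `n`, `mean`, `q25`, `q75`,
#'   `adjusted_mean`, `statistic` (F), `p_value` (the test columns repeat
#'   across a variable's group rows).
#' @export
enterotype_contrasts <- function(fit, variables, covariates = NULL) {
  labels <- if (inherits(fit, "enterotype_fit")) fit$labels else fit
  stopifnot(all(c("sample_id", "cluster") %in% names(labels)))
  aligned <- if (is.null(covariates)) {
    align_samples(labels = labels, variables = variables)
  } else {
    align_samples(labels = labels, variables = variables, covariates = covariates)
  }
  labels <- aligned$labels
  variables <- aligned$variables
  covariates <- aligned$covariates
  group <- if ("enterotype" %in% names(labels)) factor(labels$enterotype)
           else factor(labels$cluster)
  cols <- setdiff(names(variables), "sample_id")
  purrr::map_dfr(cols, function(v) {
    y <- variables[[v]]
    test <- glm_group_test(y, group, covariates)
    adj <- attr(test, "adjusted_means")
    purrr::map_dfr(levels(group), function(g) {
      yi <- y[group == g]
      tibble::tibble(variable = v, group = g, n = length(yi),
                     mean = mean(yi),
                     q25 = unname(stats::quantile(yi, 0.25)),
                     q75 = unname(stats::quantile(yi, 0.75)),
                     adjusted_mean = adj$mean[adj$group == g],
                     statistic = test$statistic, p_value = test$p_value)
    })
  })
}
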