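expand_covariates <- function(covariates, n = NULL) {
  if (is.null(covariates)) return(NULL)
  if (is.data.frame(covariates)) covariates$sample_id <- NULL
  df <- as.data.frame(covariates)
  if (ncol(df) == 0) return(NULL)
  mm <- stats::model.matrix(~ ., data = df)
  mm <- mm[, -1, drop = FALSE]  # drop intercept; indicator expansion of factors
  if (!is.null(n) && nrow(mm) != n) {
    stop("covariates have ", nrow(mm), " complete rows but ", n, " samples", call. = FALSE)
  }
  mm
}

#' Partial Spearman correlation
#'
#' Ranks `x`, `y` and every covariate column (average ranks on ties),
#' residualises the ranked `x` and `y` on the ranked covariates plus an
#' intercept by least squares, and returns the Pearson correlation of the two
#' residual vectors. The p-value comes from the t statistic on
#' `n - 2 - c` degrees of freedom (`c` = number of indicator-expanded
#' covariate columns), two-sided. With no covariates this is the classical
#' Spearman coefficient.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional data frame or matrix of covariates (categorical
#'   columns are expanded to indicators).
#' @return One-row tibble: `coefficient`, `p_value`, `n_effective`, `df`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  cm <- expand_covariates(covariates, n)
  c_cols <- if (is.null(cm)) 0L else ncol(cm)
  if (n <= c_cols + 3) stop("invalid-argument: need n > c + 3", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("degenerate-input: constant variable after ranking", call. = FALSE)
  }
  if (c_cols > 0) {
    rc <- apply(cm, 2, rank)
    design <- cbind(1, rc)
    rx <- stats::lm.fit(design, rx)$residuals
    ry <- stats::lm.fit(design, ry)$residuals
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - c_cols
  r <- max(min(r, 1), -1)
  t_stat <- r * sqrt(df / max(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(t_stat), df)
  tibble::tibble(coefficient = r, p_value = max(p, .Machine$double.xmin),
                 n_effective = n, df = df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} m p_(j) / j`, clipped at
#' 1, returned in input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("invalid-argument: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' PERMANOVA (single-factor, pseudo-F permutation test)
#'
#' Gower-centres `-d^2/2` and compares the variance explained by the factor
#' (categorical grouping or numeric regressor) against label permutations.
#' `p = (1 + #{F* >= F}) / (1 + n_perm)`; samples are put into canonical
#' (sorted id) order before permuting, so the result does not depend on input
#' row order.
#'
#' @param dm Distance matrix with sample-id dimnames.
#' @param factor Per-sample grouping (character/factor) or numeric covariate,
#'   named by sample id or in `dm` order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return One-row tibble: `statistic` (pseudo-F), `r2`, `p_value`,
#'   `n_effective`, `n_perm`.
#' @export
permanova <- function(dm, factor, n_perm = 999, seed = 1L) {
  dm <- as_distance_matrix(dm)
  orig_ids <- rownames(dm)
  if (is.null(names(factor)) && length(factor) != length(orig_ids)) {
    stop("factor length does not match distance matrix", call. = FALSE)
  }
  ids <- sort(orig_ids)
  f <- if (!is.null(names(factor))) factor[ids] else factor[match(ids, orig_ids)]
  dm <- dm[ids, ids]
  if (anyNA(f)) stop("missing factor values", call. = FALSE)
  categorical <- is.character(f) || is.factor(f) || is.logical(f)
  if (categorical) {
    f <- factor(f)
    if (nlevels(f) < 2) stop("invalid-argument: factor needs >= 2 levels", call. = FALSE)
    if (any(table(f) < 2)) stop("invalid-argument: every level needs >= 2 samples", call. = FALSE)
  }
  n <- length(ids)
  G <- -0.5 * dm^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  X <- stats::model.matrix(~ f)
  qx <- qr(X)
  H <- tcrossprod(qr.Q(qx)[, seq_len(qx$rank), drop = FALSE])
  df_m <- qx$rank - 1L
  df_r <- n - qx$rank
  ss_total <- sum(diag(G))
  f_from <- function(perm) {
    Gp <- G[perm, perm]
    ss_m <- sum(Gp * H)        # tr(H G H) = sum(H * G) for symmetric H, G
    ss_r <- ss_total - ss_m
    (ss_m / df_m) / (ss_r / df_r)
  }
  obs <- f_from(seq_len(n))
  set.seed(substream_seed(seed, "permanova"))
  perm_f <- vapply(seq_len(n_perm), function(i) f_from(sample.int(n)), numeric(1))
  p <- (1 + sum(perm_f >= obs - 1e-12)) / (1 + n_perm)
  ss_m <- sum(G * H)
  tibble::tibble(statistic = obs, r2 = ss_m / ss_total, p_value = p,
                 n_effective = n, n_perm = n_perm)
}

#' Wilcoxon-Mann-Whitney test
#'
#' U statistic with midrank ties; exact p by enumeration when the combined
#' size is at most 12 and there are no ties, otherwise the normal
#' approximation with tie and continuity correction. Two-sided.
#'
#' @param x_a,x_b Numeric vectors, both non-empty.
#' @return One-row tibble: `statistic` (U for the first group), `p_value`,
#'   `n_a`, `n_b`, `exact` (logical).
#' @export
mann_whitney <- function(x_a, x_b) {
  if (length(x_a) == 0 || length(x_b) == 0) {
    stop("invalid-argument: both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x_a, x_b)) > 0
  exact <- (length(x_a) + length(x_b) <= 12) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x_a, x_b, exact = exact,
                                            correct = TRUE, alternative = "two.sided"))
  tibble::tibble(statistic = unname(wt$statistic), p_value = min(wt$p.value, 1),
                 n_a = length(x_a), n_b = length(x_b), exact = exact)
}

#' Covariate-adjusted group comparison (partial F test)
#'
#' Ordinary least squares of `y` on intercept + covariates + group
#' indicators, compared against the covariate-only model by a partial F test.
#' Adjusted group means are model predictions with every sample assigned to
#' the group in turn, averaged over the observed covariate distribution.
#'
#' @param y Numeric response.
#' @param group Per-sample categorical grouping (>= 2 levels).
#' @param covariates Optional covariate data frame.
#' @return One-row tibble: `statistic` (F), `df1`, `df2`, `p_value`,
#'   `n_effective`; attribute `"adjusted_means"` is a tibble (group, mean).
#' @export
glm_group_test <- function(y, group, covariates = NULL) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("invalid-argument: need >= 2 groups", call. = FALSE)
  n <- length(y)
  stopifnot(length(group) == n)
  dat <- data.frame(.y = y, .group = group)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    cv$sample_id <- NULL
    stopifnot(nrow(cv) == n)
    dat <- cbind(dat, cv)
  }
  rhs_cov <- setdiff(names(dat), c(".y", ".group"))
  f_full <- stats::reformulate(c(rhs_cov, ".group"), response = ".y")
  f_red <- if (length(rhs_cov) > 0) stats::reformulate(rhs_cov, response = ".y")
           else .y ~ 1
  fit_full <- stats::lm(f_full, data = dat)
  if (anyNA(stats::coef(fit_full))) {
    aliased <- names(stats::coef(fit_full))[is.na(stats::coef(fit_full))]
    stop("degenerate-design: aliased column(s) ", paste(aliased, collapse = ", "),
         call. = FALSE)
  }
  fit_red <- stats::lm(f_red, data = dat)
  an <- stats::anova(fit_red, fit_full)
  adj <- vapply(levels(group), function(g) {
    nd <- dat
    nd$.group <- factor(g, levels = levels(group))
    mean(stats::predict(fit_full, newdata = nd))
  }, numeric(1))
  out <- tibble::tibble(statistic = an$F[2], df1 = an$Df[2],
                        df2 = an$Res.Df[2], p_value = an$`Pr(>F)`[2],
                        n_effective = n)
  attr(out, "adjusted_means") <- tibble::tibble(group = levels(group), mean = adj)
  out
}

#' All-pairs partial-correlation screen with scoped FDR
#'
#' Runs [partial_spearman()] for every (left, right) variable pair and applies
#' BH-FDR within the declared scope. The default scope corrects all pairs
#' together; passing a named character vector (left-variable name -> scope
#' label, e.g. each genus mapped to its phylum) corrects within each family
#' of left variables, the convention of taxon screens that adjust genera
#' within their phylum.
#'
#' @param left,right Numeric matrices or data frames (samples aligned; a
#'   `sample_id` column is ignored).
#' @param covariates Optional covariate data frame passed to
#'   [partial_spearman()].
#' @param fdr_scope `NULL` (one global scope) or a named character vector
#'   mapping left-variable names to scope labels.
#' @return Long tibble: `left`, `right`, `coefficient`, `p_value`, `q_value`,
#'   `n_effective`.
#' @export
correlation_screen <- function(left, right, covariates = NULL, fdr_scope = NULL) {
  as_mat <- function(x) {
    if (is.data.frame(x)) x <- x[, setdiff(names(x), "sample_id"), drop = FALSE]
    as.matrix(x)
  }
  lm_ <- as_mat(left)
  rm_ <- as_mat(right)
  stopifnot(nrow(lm_) == nrow(rm_))
  if (is.null(colnames(lm_))) colnames(lm_) <- paste0("L", seq_len(ncol(lm_)))
  if (is.null(colnames(rm_))) colnames(rm_) <- paste0("R", seq_len(ncol(rm_)))
  grid <- tidyr::expand_grid(left = colnames(lm_), right = colnames(rm_))
  res <- purrr::pmap_dfr(grid, function(left, right) {
    dplyr::bind_cols(tibble::tibble(left = left, right = right),
                     partial_spearman(lm_[, left], rm_[, right], covariates))
  })
  scope <- if (is.null(fdr_scope)) rep("all", nrow(res)) else {
    missing <- setdiff(colnames(lm_), names(fdr_scope))
    if (length(missing) > 0) {
      stop("fdr_scope missing left variable(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    unname(fdr_scope[res$left])
  }
  res$q_value <- stats::ave(res$p_value, scope, FUN = bh_fdr)
  res$df <- NULL
  res
}
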