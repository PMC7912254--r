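#' Fit the high alpha-diversity dietary pattern by reduced rank regression
#'
#' With a single response the first reduced-rank-regression factor is exact:
#' it equals the fitted direction of the least-squares regression of the
#' response on the column-standardised foods. Weights are the coefficients of
#' that direction (scaled so the score has unit variance), the score is the
#' standardised linear combination, loadings are the Pearson correlations of
#' each food with the score, and `response_r2` is the squared correlation of
#' score and response. The score is oriented so that its correlation with the
#' response is non-negative ("high diversity" points up).
#'
#' @param x Energy-adjusted log-intake matrix or tibble (a `sample_id` column
#'   is carried through to the scores), samples by food groups.
#' @param y Numeric response, one value per sample (log alpha-diversity in
#'   the canonical analysis).
#' @param response_name Label stored on the fit (default `"response"`).
#' @return An object of class `rrr_fit` with elements `food_groups`,
#'   `weights`, `loadings`, `scores` (tibble: `sample_id`, `score`),
#'   `response_r2`, `response_name`, `n`.
#' @export
fit_rrr <- function(x, y, response_name = "response") {
  ids <- NULL
  if (is.data.frame(x)) {
    ids <- x$sample_id
    x <- as.matrix(x[, setdiff(names(x), "sample_id"), drop = FALSE])
  }
  stopifnot(is.matrix(x), nrow(x) == length(y))
  n <- nrow(x)
  g <- ncol(x)
  if (is.null(ids)) ids <- rownames(x) %||% sprintf("S%03d", seq_len(n))
  if (n < g + 2) stop("invalid-argument: need n >= n_foods + 2", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds < 1e-12)) {
    stop("degenerate-design: constant column(s) ",
         paste(colnames(x)[sds < 1e-12], collapse = ", "), call. = FALSE)
  }
  xs <- scale(x)
  qx <- qr(xs)
  if (qx$rank < g) {
    collinear <- colnames(x)[qx$pivot[(qx$rank + 1):g]]
    stop("degenerate-design: collinear column(s) ", paste(collinear, collapse = ", "),
         call. = FALSE)
  }
  b <- stats::lm.fit(cbind(1, xs), y)$coefficients[-1]
  raw <- as.numeric(xs %*% b)
  s <- stats::sd(raw)
  if (s < 1e-12) stop("degenerate-design: response unexplained by foods", call. = FALSE)
  score <- (raw - mean(raw)) / s
  orient <- if (stats::cor(score, y) < 0) -1 else 1
  score <- orient * score
  weights <- orient * b / s
  loadings <- as.numeric(stats::cor(x, score))
  structure(list(
    food_groups = colnames(x),
    weights = stats::setNames(as.numeric(weights), colnames(x)),
    loadings = stats::setNames(loadings, colnames(x)),
    scores = tibble::tibble(sample_id = ids, score = score),
    response_r2 = stats::cor(score, y)^2,
    response_name = response_name,
    n = n
  ), class = "rrr_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rrr_fit <- function(x, ...) {
  cat(sprintf("<rrr_fit> %s ~ %d food groups, n = %d, response R^2 = %.3f\n",
              x$response_name, length(x$food_groups), x$n, x$response_r2))
  invisible(x)
}

#' Broom-style accessors for an RRR fit
#'
#' `tidy()` returns one row per food group with its weight and loading;
#' `glance()` returns the one-row model summary.
#'
#' @param x An `rrr_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rrr_fit <- function(x, ...) {
  tibble::tibble(food_group = x$food_groups,
                 weight = unname(x$weights),
                 loading = unname(x$loadings)) |>
    dplyr::arrange(dplyr::desc(abs(.data$loading)))
}

#' @rdname tidy.rrr_fit
#' @export
glance.rrr_fit <- function(x, ...) {
  tibble::tibble(response = x$response_name, response_r2 = x$response_r2,
                 n = x$n, n_foods = length(x$food_groups))
}

#' Main contributing food groups of a dietary pattern
#'
#' Foods with `|loading| > threshold`, split into positive and negative
#' contributors and sorted by absolute loading.
#'
#' @param fit An [fit_rrr()] result.
#' @param threshold Absolute-loading cutoff in `(0, 1]` (default 0.3, the
#'   conventional factor-loading cutoff of dietary-pattern studies).
#' @return Tibble: `food_group`, `loading`, `direction`
#'   (`"positive"`/`"negative"`), sorted by `|loading|` descending.
#' @export
main_contributors <- function(fit, threshold = 0.3) {
  stopifnot(inherits(fit, "rrr_fit"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("invalid-argument: threshold must lie in (0, 1]", call. = FALSE)
  }
  tidy.rrr_fit(fit) |>
    dplyr::filter(abs(.data$loading) > threshold) |>
    dplyr::mutate(direction = ifelse(.data$loading > 0, "positive", "negative")) |>
    dplyr::select("food_group", "loading", "direction")
}

#' Screen taxa against a dietary-pattern score
#'
#' Partial Spearman correlation of the pattern score with the clr-transformed
#' abundance of every taxon, BH-FDR within the declared scope (typically each
#' genus corrected within its phylum).
#'
#' @param scores Score tibble from [fit_rrr()] (or a named numeric vector).
#' @param clr_taxa A [composition()] at stage `"clr"`.
#' @param covariates Optional covariate tibble aligned to the samples.
#' @param fdr_scope `NULL` or named character vector mapping taxon to scope
#'   (see [correlation_screen()]).
#' @return Tibble: `taxon`, `coefficient`, `p_value`, `q_value`,
#'   `n_effective`.
#' @export
pattern_taxa_screen <- function(scores, clr_taxa, covariates = NULL, fdr_scope = NULL) {
  stopifnot(inherits(clr_taxa, "composition"))
  if (clr_taxa$stage != "clr") stop("invalid-state: clr stage required", call. = FALSE)
  if (is.data.frame(scores)) scores <- stats::setNames(scores$score, scores$sample_id)
  ids <- rownames(clr_taxa$values)
  if (!is.null(names(scores))) {
    missing <- setdiff(ids, names(scores))
    if (length(missing) > 0) stop("join-error: scores missing samples ",
                                  paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    scores <- scores[ids]
  }
  out <- correlation_screen(clr_taxa$values,
                            matrix(scores, ncol = 1, dimnames = list(ids, "score")),
                            covariates = covariates, fdr_scope = fdr_scope)
  dplyr::select(dplyr::rename(out, taxon = "left"), -"right")
}
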