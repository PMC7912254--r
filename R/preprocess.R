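#' Rarefy a feature table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (a single seeded draw, matching the common standardisation of one rarefied
#' table rather than an average over draws). Samples whose total is below
#' `depth` are dropped with a message.
#'
#' @param table A [feature_table()].
#' @param depth Target depth; `NULL` uses the minimum sample total (the
#'   cohort-minimum convention; a 222-subject 16S study of this design used
#'   5887 reads).
#' @param seed Integer seed for the subsampling draw.
#' @return A rarefied `feature_table`; attribute `"dropped"` lists removed
#'   samples, attribute `"depth"` the depth used.
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  totals <- rowSums(table$counts)
  if (is.null(depth)) depth <- min(totals)
  if (depth <= 0) stop("invalid-argument: depth must be >= 1", call. = FALSE)
  keep <- totals >= depth
  if (!all(keep)) {
    message("rarefy: dropped ", sum(!keep), " sample(s) below depth ", depth)
  }
  if (!any(keep)) stop("no sample reaches the rarefaction depth", call. = FALSE)
  counts <- table$counts[keep, , drop = FALSE]
  set.seed(substream_seed(seed, "rarefy"))
  exact <- rowSums(counts) == depth
  if (any(!exact)) {
    # vegan warns when the smallest positive count exceeds 1 (a heuristic for
    # pre-normalised data); our inputs are genuine counts, so silence it
    counts[!exact, ] <- withCallingHandlers(
      vegan::rrarefy(counts[!exact, , drop = FALSE], depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) invokeRestart("muffleWarning")
      })
  }
  out <- feature_table(counts, table$lineage)
  attr(out, "dropped") <- rownames(table$counts)[!keep]
  attr(out, "depth") <- depth
  out
}

#' Aggregate counts to a taxonomic rank
#'
#' Counts are summed over taxa sharing the rank name; taxa unassigned at the
#' rank pool into `"unclassified"`. Per-sample totals are conserved.
#'
#' @param table A [feature_table()].
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`.
#' @return A `feature_table` whose taxa are the rank's names (lineage keeps
#'   the ranks at or above `rank` when they are constant within a group).
#' @export
aggregate_taxa <- function(table, rank) {
  stopifnot(inherits(table, "feature_table"))
  if (!rank %in% rank_names()) {
    stop("invalid-argument: unknown rank '", rank, "'", call. = FALSE)
  }
  groups <- table$lineage[[rank]]
  agg <- t(rowsum(t(table$counts), groups))
  higher <- rank_names()[seq_len(match(rank, rank_names()))]
  lin <- unique(table$lineage[, c(higher)])
  lin <- lin[!duplicated(lin[[rank]]), , drop = FALSE]
  lineage <- tibble::tibble(taxon_id = colnames(agg))
  for (r in higher) {
    lineage[[r]] <- lin[[r]][match(colnames(agg), lin[[rank]])]
  }
  lineage[[rank]] <- colnames(agg)
  feature_table(agg, lineage)
}

#' Convert counts to relative abundances
#'
#' @param table A [feature_table()] (or a counts matrix with dimnames).
#' @return A [composition()] at stage `"proportions"`, carrying the original
#'   per-sample totals.
#' @export
to_proportions <- function(table) {
  counts <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    stop("degenerate-input: all-zero sample '",
         rownames(counts)[which(totals <= 0)[1]], "'", call. = FALSE)
  }
  composition(counts / totals, "proportions", totals = stats::setNames(totals, rownames(counts)))
}

#' Bayesian-multiplicative replacement of compositional zeros
#'
#' Geometric Bayesian-multiplicative replacement with a per-part prior
#' `s_j` (Jeffreys `0.5` by default): in sample `i` with original count total
#' `N_i`, each zero part `j` becomes `delta_ij = s_j / (N_i + sum(s))` and the
#' non-zero parts are multiplied by `1 - sum(delta_i)` so the row still sums
#' to 1 and all ratios between non-zero parts are preserved exactly.
#'
#' @param cm A [composition()] at stage `"proportions"` with totals carried
#'   from the source counts.
#' @param prior_strength Scalar or per-part prior strength (default 0.5).
#' @return A `composition` at stage `"zero_replaced"`.
#' @export
replace_zeros <- function(cm, prior_strength = 0.5) {
  stopifnot(inherits(cm, "composition"))
  if (cm$stage != "proportions") {
    stop("invalid-state: replace_zeros expects the proportions stage", call. = FALSE)
  }
  if (is.null(cm$totals)) stop("composition lacks original count totals", call. = FALSE)
  if (any(prior_strength <= 0)) stop("invalid-argument: prior_strength must be positive", call. = FALSE)
  D <- ncol(cm$values)
  s <- rep_len(prior_strength, D)
  S <- sum(s)
  vals <- cm$values
  for (i in seq_len(nrow(vals))) {
    zero <- vals[i, ] == 0
    if (!any(zero)) next
    if (all(zero)) stop("degenerate-input: entirely zero sample", call. = FALSE)
    delta <- s[zero] / (cm$totals[i] + S)
    vals[i, zero] <- delta
    vals[i, !zero] <- vals[i, !zero] * (1 - sum(delta))
  }
  composition(vals, "zero_replaced", totals = cm$totals)
}

#' Centred log-ratio transform
#'
#' `clr_ij = ln(x_ij) - mean_j ln(x_ij)`; rows sum to zero.
#'
#' @param cm A [composition()] at stage `"zero_replaced"` (all entries
#'   strictly positive; replace zeros first).
#' @return A `composition` at stage `"clr"`.
#' @export
clr_transform <- function(cm) {
  stopifnot(inherits(cm, "composition"))
  if (cm$stage == "clr") return(cm)
  if (any(cm$values <= 0)) {
    stop("invalid-state: non-positive entries; run replace_zeros() first", call. = FALSE)
  }
  lx <- log(cm$values)
  out <- lx - rowMeans(lx)
  composition(out, "clr", totals = cm$totals)
}

#' Pairwise clr log-ratio (e.g. the Firmicutes-to-Bacteroidetes ratio)
#'
#' The difference of two clr coordinates equals `ln(x_a / x_b)` identically,
#' so this is the clr-transformed F/B ratio when `part_a = "Firmicutes"`,
#' `part_b = "Bacteroidetes"` on phylum-level data.
#'
#' @param cm A [composition()] at stage `"clr"`.
#' @param part_a,part_b Part (column) names.
#' @return Named numeric vector, one value per sample.
#' @export
clr_log_ratio <- function(cm, part_a, part_b) {
  stopifnot(inherits(cm, "composition"))
  if (cm$stage != "clr") stop("invalid-state: clr stage required", call. = FALSE)
  missing <- setdiff(c(part_a, part_b), colnames(cm$values))
  if (length(missing) > 0) {
    stop("invalid-argument: missing part(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cm$values[, part_a] - cm$values[, part_b]
}

#' Log-transform and energy-adjust dietary intakes (residual method)
#'
#' Each food group's intake is log-transformed (zeros offset by half the
#' smallest positive value in the column) and regressed on log total energy
#' by ordinary least squares; the adjusted value is the residual plus the
#' fitted value at the sample-mean log energy, so columns keep their original
#' location while their correlation with log energy becomes exactly zero.
#'
#' @param diet A diet tibble as returned by [read_diet()] or
#'   [generate_diet()] (`sample_id`, `total_energy`, then intake columns).
#' @param columns Intake columns to adjust; default every column except
#'   `sample_id` and `total_energy`.
#' @return Tibble with `sample_id` and the adjusted log-scale columns.
#' @export
adjust_diet <- function(diet, columns = NULL) {
  stopifnot(is.data.frame(diet), all(c("sample_id", "total_energy") %in% names(diet)))
  if (any(diet$total_energy <= 0)) stop("total_energy must be positive", call. = FALSE)
  log_energy <- log(diet$total_energy)
  if (stats::sd(log_energy) < 1e-12) {
    stop("degenerate-design: total energy is constant across samples", call. = FALSE)
  }
  if (is.null(columns)) columns <- setdiff(names(diet), c("sample_id", "total_energy"))
  centered <- log_energy - mean(log_energy)
  out <- tibble::tibble(sample_id = diet$sample_id)
  for (col in columns) {
    x <- diet[[col]]
    if (any(x < 0)) stop("negative intake in column '", col, "'", call. = FALSE)
    if (any(x == 0)) {
      pos <- x[x > 0]
      if (length(pos) == 0) stop("column '", col, "' is entirely zero", call. = FALSE)
      x <- x + min(pos) / 2
    }
    lx <- log(x)
    fit <- stats::lm.fit(cbind(1, centered), lx)
    # residual + fitted value at mean log energy (= intercept)
    out[[col]] <- as.numeric(fit$residuals + fit$coefficients[1])
  }
  out
}
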