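#' Construct a feature table
#'
#' The central container of the pipeline: a samples-by-taxa matrix of
#' non-negative integer counts (OTU or aggregated-taxon counts) together with
#' the taxonomic lineage of every taxon.
#'
#' @param counts Numeric matrix, rows = samples, columns = taxa. Entries must
#'   be non-negative integers; dimnames are required and must be unique.
#' @param lineage A data frame with a `taxon_id` column matching the columns of
#'   `counts` and character columns `phylum`, `class`, `order`, `family`,
#'   `genus`. Ranks without an assignment carry the sentinel `"unclassified"`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(counts, lineage = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry sample ids (rownames) and taxon ids (colnames)", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon ids", call. = FALSE)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', taxon '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]), call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at sample '%s', taxon '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]), call. = FALSE)
  }
  storage.mode(counts) <- "double"
  counts <- round(counts)
  lineage <- normalize_lineage(lineage, colnames(counts))
  structure(list(counts = counts, lineage = lineage), class = "feature_table")
}

rank_names <- function() c("phylum", "class", "order", "family", "genus")

normalize_lineage <- function(lineage, taxon_ids) {
  if (is.null(lineage)) {
    lineage <- tibble::tibble(taxon_id = taxon_ids)
  }
  lineage <- tibble::as_tibble(lineage)
  if (!"taxon_id" %in% names(lineage)) stop("lineage needs a `taxon_id` column", call. = FALSE)
  missing <- setdiff(taxon_ids, lineage$taxon_id)
  if (length(missing) > 0) {
    stop("lineage missing taxa: ", paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  lineage <- lineage[match(taxon_ids, lineage$taxon_id), , drop = FALSE]
  for (r in rank_names()) {
    if (!r %in% names(lineage)) lineage[[r]] <- "unclassified"
    v <- as.character(lineage[[r]])
    v[is.na(v) | v == ""] <- "unclassified"
    lineage[[r]] <- v
  }
  lineage[, c("taxon_id", rank_names())]
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d taxa; depth range [%s, %s]\n",
              nrow(x$counts), ncol(x$counts),
              format(min(rowSums(x$counts))), format(max(rowSums(x$counts)))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

sample_ids <- function(x) {
  if (inherits(x, "feature_table")) return(rownames(x$counts))
  if (inherits(x, "composition")) return(rownames(x$values))
  if (is.matrix(x)) return(rownames(x))
  if (is.data.frame(x)) return(x$sample_id)
  stop("cannot extract sample ids", call. = FALSE)
}

#' Subset a feature table by sample
#'
#' @param x A [feature_table()].
#' @param samples Character vector of sample ids to keep, in order.
#' @return A `feature_table` restricted to `samples`.
#' @export
ft_subset <- function(x, samples) {
  stopifnot(inherits(x, "feature_table"))
  missing <- setdiff(samples, rownames(x$counts))
  if (length(missing) > 0) {
    stop("unknown samples: ", paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  feature_table(x$counts[samples, , drop = FALSE], x$lineage)
}

#' Construct a composition matrix
#'
#' Rows are samples on the unit simplex (stage `"proportions"` or
#' `"zero_replaced"`) or centred log-ratios summing to zero (stage `"clr"`).
#' The per-sample count totals of the source table are carried along because
#' the zero-replacement formula needs them.
#'
#' @param values Numeric matrix, rows = samples, columns = parts.
#' @param stage One of `"proportions"`, `"zero_replaced"`, `"clr"`.
#' @param totals Per-sample original count totals (numeric, named or in row
#'   order).
#' @return An object of class `composition`.
#' @export
composition <- function(values, stage = c("proportions", "zero_replaced", "clr"),
                        totals = NULL) {
  stage <- match.arg(stage)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample and part ids", call. = FALSE)
  }
  if (stage %in% c("proportions", "zero_replaced")) {
    if (any(values < 0)) stop("negative proportion", call. = FALSE)
    rs <- rowSums(values)
    if (any(abs(rs - 1) > 1e-10)) {
      stop("composition rows must sum to 1 (worst deviation ",
           format(max(abs(rs - 1))), ")", call. = FALSE)
    }
    if (stage == "zero_replaced" && any(values <= 0)) {
      stop("zero_replaced stage requires strictly positive entries", call. = FALSE)
    }
  } else {
    rs <- rowSums(values)
    if (any(abs(rs) > 1e-8)) stop("clr rows must sum to 0", call. = FALSE)
  }
  if (!is.null(totals)) {
    if (!is.null(names(totals))) totals <- totals[rownames(values)]
    stopifnot(length(totals) == nrow(values))
  }
  structure(list(values = values, stage = stage, totals = totals),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("<composition:%s> %d samples x %d parts\n", x$stage,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Validate a distance matrix
#'
#' @param values Square numeric matrix with identical row and column sample
#'   ids, symmetric within `1e-10`, zero diagonal, non-negative entries.
#' @return The validated matrix, invisibly of class `matrix`.
#' @export
as_distance_matrix <- function(values) {
  if (inherits(values, "dist")) values <- as.matrix(values)
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(values))) stop("distance matrix needs sample ids", call. = FALSE)
  if (!identical(rownames(values), colnames(values))) {
    stop("row and column sample ids differ", call. = FALSE)
  }
  if (max(abs(values - t(values))) > 1e-10) stop("distance matrix not symmetric", call. = FALSE)
  if (max(abs(diag(values))) > 1e-12) stop("distance matrix diagonal not zero", call. = FALSE)
  if (any(values < -1e-12)) stop("negative distances", call. = FALSE)
  values[values < 0] <- 0
  diag(values) <- 0
  values
}

#' Align tables on their shared samples
#'
#' Every multi-table stage first intersects sample ids and puts all inputs in
#' the same (sorted) order; samples present in only some tables are dropped
#' with a message, mirroring how cohort studies discard subjects with
#' incomplete records.
#'
#' @param ... Named objects carrying sample ids (feature tables, compositions,
#'   matrices with rownames, or data frames with a `sample_id` column).
#' @return Named list of the inputs restricted and reordered to the common
#'   samples (attribute `"dropped"` counts discards per input).
#' @export
align_samples <- function(...) {
  inputs <- list(...)
  stopifnot(length(inputs) >= 1, !is.null(names(inputs)))
  ids <- lapply(inputs, sample_ids)
  common <- sort(Reduce(intersect, ids))
  if (length(common) == 0) {
    stop("join-error: no samples shared across ", paste(names(inputs), collapse = ", "),
         call. = FALSE)
  }
  dropped <- vapply(ids, function(v) length(setdiff(v, common)), integer(1))
  if (any(dropped > 0)) {
    message("align_samples: dropped ",
            paste(sprintf("%d from %s", dropped[dropped > 0],
                          names(inputs)[dropped > 0]), collapse = ", "),
            "; ", length(common), " samples retained")
  }
  out <- lapply(inputs, function(x) {
    if (inherits(x, "feature_table")) return(ft_subset(x, common))
    if (inherits(x, "composition")) {
      return(composition(x$values[common, , drop = FALSE], x$stage,
                         x$totals[match(common, rownames(x$values))]))
    }
    if (is.matrix(x)) {
      if (identical(rownames(x), colnames(x))) return(x[common, common, drop = FALSE])
      return(x[common, , drop = FALSE])
    }
    if (is.data.frame(x)) return(x[match(common, x$sample_id), , drop = FALSE])
    stop("unsupported input type", call. = FALSE)
  })
  attr(out, "dropped") <- dropped
  out
}

# Derive independent sub-stream seeds from one root seed so that adding a
# consumer never perturbs another's draws. Kept below 2^31 - 1.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}
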