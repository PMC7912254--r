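#' Chao1 richness estimator (bias-corrected)
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with `F1`/`F2` the singleton and
#' doubleton counts; the bias-corrected form is defined even when no
#' doubletons are present.
#'
#' @param counts Non-negative integer vector with at least one positive entry.
#' @return The Chao1 estimate (never below observed richness).
#' @export
chao1 <- function(counts) {
  if (all(counts == 0)) stop("degenerate-input: all-zero sample", call. = FALSE)
  if (any(counts < 0)) stop("invalid-argument: negative counts", call. = FALSE)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index
#'
#' `H = -sum p_i log p_i` over the non-zero proportions; natural log by
#' default.
#'
#' @param counts Non-negative vector with at least one positive entry
#'   (counts or proportions).
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index in `[0, log_base(D)]`.
#' @export
shannon <- function(counts, base = exp(1)) {
  if (all(counts == 0)) stop("degenerate-input: all-zero sample", call. = FALSE)
  if (any(counts < 0)) stop("invalid-argument: negative counts", call. = FALSE)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Precompute the branch structure of a tree
#'
#' Returns, for every edge, its length and the set of leaves descending from
#' it (as a leaves-by-edges incidence matrix). Faith PD and both UniFrac
#' variants are linear algebra on this structure. Uses the rooted convention:
#' every edge of the rooted tree counts; the root node itself carries no
#' length.
#'
#' @param tree An `ape::phylo` rooted tree with branch lengths.
#' @return List with `incidence` (leaves x edges, 0/1), `lengths` (per edge)
#'   and `tip_labels`.
#' @export
tree_branches <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree lacks branch lengths", call. = FALSE)
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  n_edge <- nrow(tr$edge)
  inc <- matrix(0, n, n_edge)
  desc <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in seq_len(n_edge)) {
    child <- tr$edge[e, 2]
    parent <- tr$edge[e, 1]
    inc[desc[[child]], e] <- 1
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  rownames(inc) <- tr$tip.label
  list(incidence = inc, lengths = tr$edge.length, tip_labels = tr$tip.label)
}

check_taxa_in_tree <- function(mat, branches) {
  missing <- setdiff(colnames(mat), branches$tip_labels)
  if (length(missing) > 0) {
    stop("invalid-argument: taxa missing from tree: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
}

counts_matrix <- function(table) {
  if (inherits(table, "feature_table")) table$counts else as.matrix(table)
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the union of root-to-leaf paths over a
#' sample's observed taxa.
#'
#' @param counts Named non-negative vector (or samples-by-taxa matrix) of
#'   counts; names must be tree leaves.
#' @param tree An `ape::phylo` rooted tree, or a [tree_branches()] structure.
#' @return Numeric: one PD value per sample.
#' @export
faith_pd <- function(counts, tree) {
  br <- if (inherits(tree, "phylo")) tree_branches(tree) else tree
  mat <- if (is.matrix(counts)) counts else matrix(counts, 1, dimnames = list("s", names(counts)))
  check_taxa_in_tree(mat, br)
  if (any(rowSums(mat) == 0)) stop("degenerate-input: all-zero sample", call. = FALSE)
  inc <- br$incidence[colnames(mat), , drop = FALSE]
  present <- (mat > 0) %*% inc > 0
  pd <- as.numeric(present %*% br$lengths)
  if (is.matrix(counts)) stats::setNames(pd, rownames(counts)) else pd[1]
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(A, B) = 1 - 2 sum min(p_A, p_B) / sum (p_A + p_B)` on relative
#' abundances (computed through `vegan::vegdist`).
#'
#' @param cm A [composition()] at stage `"proportions"` (or a matrix of
#'   row-normalised abundances).
#' @return A symmetric distance matrix with sample-id dimnames.
#' @export
bray_curtis <- function(cm) {
  vals <- if (inherits(cm, "composition")) cm$values else as.matrix(cm)
  as_distance_matrix(as.matrix(vegan::vegdist(vals, method = "bray")))
}

#' UniFrac distance matrices
#'
#' Unweighted UniFrac: fraction of total branch length unique to exactly one
#' of the two samples' observed leaf sets, out of the branch length present
#' in either. Weighted UniFrac (raw): `sum_b l_b |P_A(b) - P_B(b)|` with
#' `P_X(b)` the proportion of sample X descending from branch `b`; the
#' normalised form divides by `sum_b l_b (P_A(b) + P_B(b))`.
#'
#' @param table A [feature_table()] or counts matrix.
#' @param tree An `ape::phylo` rooted tree or [tree_branches()] structure.
#' @param normalized For the weighted variant: divide by the pairwise total
#'   (default `FALSE`, the raw form).
#' @return A symmetric distance matrix with sample-id dimnames.
#' @export
unweighted_unifrac <- function(table, tree) {
  br <- if (inherits(tree, "phylo")) tree_branches(tree) else tree
  mat <- counts_matrix(table)
  check_taxa_in_tree(mat, br)
  inc <- br$incidence[colnames(mat), , drop = FALSE]
  present <- ((mat > 0) %*% inc > 0) * 1           # samples x edges
  pw <- sweep(present, 2, br$lengths, `*`)         # length-weighted presence
  shared <- pw %*% t(present)                      # sum l over branches in both
  tot <- rowSums(pw)
  union <- outer(tot, tot, `+`) - shared
  d <- ifelse(union > 0, 1 - shared / union, 0)
  dimnames(d) <- list(rownames(mat), rownames(mat))
  as_distance_matrix((d + t(d)) / 2)
}

#' @rdname unweighted_unifrac
#' @export
weighted_unifrac <- function(table, tree, normalized = FALSE) {
  br <- if (inherits(tree, "phylo")) tree_branches(tree) else tree
  mat <- counts_matrix(table)
  check_taxa_in_tree(mat, br)
  props <- mat / rowSums(mat)
  inc <- br$incidence[colnames(mat), , drop = FALSE]
  pb <- props %*% inc                              # samples x edges proportions
  raw <- as.matrix(stats::dist(sweep(pb, 2, br$lengths, `*`), method = "manhattan"))
  if (!normalized) {
    dimnames(raw) <- list(rownames(mat), rownames(mat))
    return(as_distance_matrix(raw))
  }
  tot <- rowSums(sweep(pb, 2, br$lengths, `*`))
  denom <- outer(tot, tot, `+`)
  d <- ifelse(denom > 0, raw / denom, 0)
  dimnames(d) <- list(rownames(mat), rownames(mat))
  as_distance_matrix(d)
}

#' Alpha-diversity table
#'
#' Computes observed richness, Chao1, Shannon and (when a tree is supplied)
#' Faith PD for every sample of a feature table. Metadata attributes record
#' the Shannon log base.
#'
#' @param table A [feature_table()] (typically rarefied).
#' @param tree Optional `ape::phylo` tree for Faith PD.
#' @param shannon_base Log base for the Shannon index (default natural log).
#' @return Tibble with columns `sample_id`, `observed`, `chao1`, `shannon`
#'   and, if a tree is given, `faith_pd`.
#' @export
alpha_diversity <- function(table, tree = NULL, shannon_base = exp(1)) {
  counts <- counts_matrix(table)
  out <- tibble::tibble(
    sample_id = rownames(counts),
    observed = as.numeric(rowSums(counts > 0)),
    chao1 = apply(counts, 1, chao1),
    shannon = apply(counts, 1, shannon, base = shannon_base)
  )
  if (!is.null(tree)) out$faith_pd <- as.numeric(faith_pd(counts, tree))
  attr(out, "shannon_base") <- shannon_base
  out
}

#' Beta-diversity dispatcher
#'
#' @param table A [feature_table()] (rarefied counts).
#' @param metric One of `"bray_curtis"`, `"unweighted_unifrac"`,
#'   `"weighted_unifrac"`.
#' @param tree Tree, required for the UniFrac metrics.
#' @param normalized Passed to [weighted_unifrac()].
#' @return A symmetric distance matrix.
#' @export
beta_diversity <- function(table, metric = c("bray_curtis", "unweighted_unifrac",
                                             "weighted_unifrac"),
                           tree = NULL, normalized = FALSE) {
  metric <- match.arg(metric)
  if (metric == "bray_curtis") return(bray_curtis(to_proportions(table)))
  if (is.null(tree)) stop("UniFrac metrics require a tree", call. = FALSE)
  switch(metric,
         unweighted_unifrac = unweighted_unifrac(table, tree),
         weighted_unifrac = weighted_unifrac(table, tree, normalized = normalized))
}
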