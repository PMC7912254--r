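# Independent oracles used by the equivalence tests. These deliberately take
# a different computational route than the package (explicit per-branch
# enumeration via phangorn descendant queries, literal step-up definitions,
# full assignment enumeration).

brute_unifrac <- function(tree, xa, xb, weighted = FALSE, normalized = FALSE) {
  xa <- xa[tree$tip.label]
  xb <- xb[tree$tip.label]
  u <- 0
  tot <- 0
  for (e in seq_len(nrow(tree$edge))) {
    node <- tree$edge[e, 2]
    tips <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
    l <- tree$edge.length[e]
    if (!weighted) {
      a <- any(xa[tips] > 0)
      b <- any(xb[tips] > 0)
      if (a || b) {
        tot <- tot + l
        if (xor(a, b)) u <- u + l
      }
    } else {
      pa <- sum(xa[tips]) / sum(xa)
      pb <- sum(xb[tips]) / sum(xb)
      u <- u + l * abs(pa - pb)
      tot <- tot + l * (pa + pb)
    }
  }
  if (!weighted) return(if (tot > 0) u / tot else 0)
  if (normalized) u / tot else u
}

brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact two-sided Mann-Whitney p by enumerating every group assignment.
brute_mw <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, u_of)
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

random_rooted_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, rooted = TRUE, br = function(k) stats::runif(k, 0.1, 2))
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}

random_counts_row <- function(taxa, sparse = TRUE) {
  x <- stats::rpois(length(taxa), lambda = 5)
  if (sparse) x[stats::runif(length(taxa)) < 0.3] <- 0
  if (all(x == 0)) x[sample.int(length(x), 1)] <- 1
  stats::setNames(x, taxa)
}
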