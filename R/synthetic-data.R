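#' Configuration of a synthetic diet-microbiome study
#'
#' Defines every knob of the synthetic cohort: a community of `n_taxa` taxa on
#' a random phylogeny, `n_samples` subjects split into planted enterotypes,
#' Dirichlet-multinomial counts, and a 25-food-group intake table carrying a
#' planted food-pattern -> community-evenness signal. Defaults emulate the
#' shape of a 222-subject adult cohort with three enterotypes dominated by
#' *Bacteroides*, *Prevotella* and *Ruminococcus*, and four dominant phyla
#' ordered Bacteroidetes > Firmicutes > Proteobacteria > Actinobacteria.
#'
#' @param n_samples Number of subjects (default 222).
#' @param n_taxa Number of tree leaves / OTUs (default 200).
#' @param n_food_groups Number of food groups (default 25; the generator's
#'   built-in group names require exactly 25).
#' @param enterotype_proportions Simplex vector, one entry per planted
#'   enterotype; must sum to 1 within `1e-12`.
#' @param dominant_genera Character vector, one genus per enterotype, whose
#'   clade is boosted in that enterotype's mean composition.
#' @param dominant_boost Multiplicative boost applied to the dominant genus
#'   clade in its own enterotype's Dirichlet mean (default 12; large enough
#'   that the planted communities form clearly separated clusters in
#'   ordination space).
#' @param concentration Dirichlet precision of per-sample compositions around
#'   the enterotype mean (default 150). A per-sample latent diversity factor
#'   modulates it multiplicatively, so evenness varies between subjects.
#' @param latent_sd Log-scale spread of the latent diversity factor
#'   (default 0.75).
#' @param diet_effect Strength of the planted association between the dietary
#'   pattern foods and latent diversity (default 1; 0 plants no signal).
#' @param depth_range Integer pair of per-sample sequencing depth bounds
#'   (default `c(6000, 20000)`; the lower bound stays above the 5887-read
#'   rarefaction depth used downstream).
#' @param pattern_weights Optional named per-food-group weight vector for the
#'   planted pattern; `NULL` uses the built-in plant (positive weights on
#'   fermented legumes, vegetables, potatoes, seaweeds, nuts/seeds and tea,
#'   negative on non-alcoholic beverages).
#' @param seed Integer root seed; every component draws from an independent
#'   sub-stream derived from it.
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(n_samples = 222,
                         n_taxa = 200,
                         n_food_groups = 25,
                         enterotype_proportions = c(0.40, 0.33, 0.27),
                         dominant_genera = c("Bacteroides", "Prevotella", "Ruminococcus"),
                         dominant_boost = 12,
                         concentration = 150,
                         latent_sd = 0.75,
                         diet_effect = 1,
                         depth_range = c(6000L, 20000L),
                         pattern_weights = NULL,
                         seed = 1L) {
  stopifnot(n_samples >= 1, n_taxa >= 2, n_food_groups >= 1)
  if (abs(sum(enterotype_proportions) - 1) > 1e-12) {
    stop("enterotype_proportions must sum to 1", call. = FALSE)
  }
  if (any(enterotype_proportions <= 0)) stop("enterotype proportions must be positive", call. = FALSE)
  if (length(dominant_genera) != length(enterotype_proportions)) {
    stop("one dominant genus per enterotype required", call. = FALSE)
  }
  if (anyDuplicated(dominant_genera)) stop("dominant genera must be distinct", call. = FALSE)
  stopifnot(length(depth_range) == 2, depth_range[1] >= 1, depth_range[2] >= depth_range[1])
  stopifnot(concentration > 0, dominant_boost > 0, latent_sd >= 0)
  structure(list(
    n_samples = as.integer(n_samples), n_taxa = as.integer(n_taxa),
    n_food_groups = as.integer(n_food_groups),
    enterotype_proportions = enterotype_proportions,
    dominant_genera = dominant_genera, dominant_boost = dominant_boost,
    concentration = concentration, latent_sd = latent_sd,
    diet_effect = diet_effect,
    depth_range = as.integer(depth_range),
    pattern_weights = pattern_weights, seed = as.integer(seed)
  ), class = "study_config")
}

phylum_profile <- function() {
  # richness share of leaves / abundance mass per phylum
  tibble::tibble(
    phylum = c("Bacteroidetes", "Firmicutes", "Proteobacteria", "Actinobacteria"),
    leaf_share = c(0.30, 0.48, 0.13, 0.09),
    mass = c(0.42, 0.51, 0.055, 0.015)
  )
}

named_genera <- function() {
  list(
    Bacteroidetes = c("Bacteroides", "Prevotella", "Tannerella", "Parabacteroides"),
    Firmicutes = c("Ruminococcus", "Lactobacillus", "Eubacterium",
                   "Faecalibacterium", "Blautia", "Roseburia", "Clostridium"),
    Proteobacteria = c("Escherichia", "Sutterella"),
    Actinobacteria = c("Bifidobacterium", "Collinsella")
  )
}

node_children <- function(tr, node) tr$edge[tr$edge[, 1] == node, 2]

node_tips <- function(tr, node) {
  n_tip <- length(tr$tip.label)
  if (node <= n_tip) return(node)
  unlist(lapply(node_children(tr, node), node_tips, tr = tr))
}

# Split the clade under `node` into sub-clades of at most `max_size` tips.
clade_chunks <- function(tr, node, max_size) {
  n_tip <- length(tr$tip.label)
  tips <- node_tips(tr, node)
  if (length(tips) <= max_size || node <= n_tip) return(list(tips))
  unlist(lapply(node_children(tr, node), clade_chunks, tr = tr, max_size = max_size),
         recursive = FALSE)
}

rexp_branches <- function(n) stats::rexp(n, rate = 10)

random_subtree <- function(tip_ids) {
  n <- length(tip_ids)
  if (n == 1) {
    return(list(newick = sprintf("%s:%.6f", tip_ids, rexp_branches(1)), tree = NULL))
  }
  tr <- ape::rtree(n, rooted = TRUE, br = rexp_branches)
  tr$tip.label <- tip_ids[as.integer(sub("^t", "", tr$tip.label))]
  list(newick = sub(";$", "", ape::write.tree(tr)), tree = tr)
}

# Nested clade partition of one phylum subtree into class/order/family/genus.
assign_ranks <- function(tr, tip_ids, phylum) {
  n <- length(tip_ids)
  lin <- tibble::tibble(taxon_id = tip_ids, phylum = phylum,
                        class = NA_character_, order = NA_character_,
                        family = NA_character_, genus = NA_character_)
  if (is.null(tr)) {  # single-tip phylum
    lin$class <- paste0(phylum, "_c1"); lin$order <- paste0(phylum, "_o1")
    lin$family <- paste0(phylum, "_f1"); lin$genus <- paste0(phylum, "_g1")
    return(lin)
  }
  root <- length(tr$tip.label) + 1L
  sizes <- c(class = 60L, order = 30L, family = 12L, genus = 6L)
  nest <- function(nodesets, max_size) {
    unlist(lapply(nodesets, function(tips) {
      # re-chunk a tip set by finding its spanning structure: chunk from root,
      # keeping only chunks inside this tip set
      chunks <- clade_chunks(tr, root, max_size)
      kept <- lapply(chunks, function(ch) intersect(ch, tips))
      kept[lengths(kept) > 0]
    }), recursive = FALSE)
  }
  classes <- clade_chunks(tr, root, sizes["class"])
  orders <- nest(classes, sizes["order"])
  families <- nest(orders, sizes["family"])
  genera <- nest(families, sizes["genus"])
  put <- function(groups, rank, labeller) {
    for (i in seq_along(groups)) {
      lin[[rank]][match(tr$tip.label[groups[[i]]], lin$taxon_id)] <<- labeller(i)
    }
  }
  put(classes, "class", function(i) sprintf("%s_c%d", phylum, i))
  put(orders, "order", function(i) sprintf("%s_o%d", phylum, i))
  put(families, "family", function(i) sprintf("%s_f%d", phylum, i))
  # name the largest genera with recognisable names, the rest synthetically
  ord <- order(lengths(genera), decreasing = TRUE)
  known <- named_genera()[[phylum]]
  gnames <- character(length(genera))
  gnames[ord] <- c(known, sprintf("%s_g%02d", phylum, seq_len(max(0, length(genera) - length(known)))))[
    seq_along(genera)]
  put(genera, "genus", function(i) gnames[i])
  lin
}

#' Generate a random rooted phylogeny with synthetic lineages
#'
#' Builds one random binary subtree per phylum (exponential branch lengths)
#' and joins them under a common root; clades within each phylum subtree are
#' recursively partitioned into class/order/family/genus so that every rank is
#' monophyletic. The largest genera receive recognisable gut-genus names
#' (*Bacteroides*, *Prevotella*, *Ruminococcus*, ...), which downstream
#' enterotype labelling uses.
#'
#' @param n_taxa Number of leaves (at least 2).
#' @param seed Integer seed.
#' @return An `ape::phylo` tree with `n_taxa` tips named `otu0001`, ... and an
#'   attribute `"lineage"` (tibble with `taxon_id` and the five ranks).
#' @export
generate_tree <- function(n_taxa, seed = 1L) {
  if (!is.numeric(n_taxa) || n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  n_taxa <- as.integer(n_taxa)
  set.seed(substream_seed(seed, "tree"))
  prof <- phylum_profile()
  k_phy <- min(nrow(prof), n_taxa)
  sizes <- pmax(1L, round(prof$leaf_share[seq_len(k_phy)] / sum(prof$leaf_share[seq_len(k_phy)]) * n_taxa))
  while (sum(sizes) != n_taxa) {
    i <- which.max(sizes)
    sizes[i] <- sizes[i] + sign(n_taxa - sum(sizes))
  }
  ids <- sprintf("otu%04d", seq_len(n_taxa))
  id_split <- split(ids, rep(seq_len(k_phy), sizes))
  subs <- lapply(id_split, random_subtree)
  lineage <- dplyr::bind_rows(lapply(seq_len(k_phy), function(i) {
    assign_ranks(subs[[i]]$tree, id_split[[i]], prof$phylum[i])
  }))
  # join subtree newick strings pairwise under a root
  parts <- vapply(subs, `[[`, "", "newick")
  while (length(parts) > 1) {
    joined <- sprintf("(%s:%.6f,%s:%.6f)", parts[1], rexp_branches(1),
                      parts[2], rexp_branches(1))
    parts <- c(joined, parts[-(1:2)])
  }
  tree <- ape::read.tree(text = paste0(parts, ";"))
  lineage <- lineage[match(ids, lineage$taxon_id), ]
  attr(tree, "lineage") <- lineage
  tree
}

dirichlet_row <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate enterotype-structured counts with a latent diversity gradient
#'
#' Each sample draws an enterotype label, then a composition from a Dirichlet
#' centred on that enterotype's mean (the dominant genus clade boosted by
#' `dominant_boost`), with per-sample precision
#' `concentration * exp(latent_sd * z)` where `z` is the sample's latent
#' diversity. Low precision yields spiky, uneven communities, so `z` drives
#' true evenness rather than any diversity statistic directly. Counts are
#' multinomial at a depth drawn uniformly from `depth_range`.
#'
#' @param config A [study_config()].
#' @param tree A tree from [generate_tree()] with its lineage attribute.
#' @return List with `table` (a [feature_table()]) and `truth` (tibble with
#'   `sample_id`, `enterotype` in `1..k`, `latent_diversity`).
#' @export
generate_counts <- function(config, tree) {
  stopifnot(inherits(config, "study_config"))
  lineage <- attr(tree, "lineage")
  if (is.null(lineage)) stop("tree lacks a lineage attribute", call. = FALSE)
  if (length(tree$tip.label) != config$n_taxa) {
    stop("tree leaf count does not match config$n_taxa", call. = FALSE)
  }
  missing <- setdiff(config$dominant_genera, lineage$genus)
  if (length(missing) > 0) {
    stop("dominant genus not in tree lineage: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  set.seed(substream_seed(config$seed, "counts"))
  ids <- tree$tip.label
  lineage <- lineage[match(ids, lineage$taxon_id), ]
  prof <- phylum_profile()
  mass <- prof$mass[match(lineage$phylum, prof$phylum)]
  mass[is.na(mass)] <- min(prof$mass)
  # lognormal weights normalised within phylum, scaled to the phylum's mass
  w <- exp(stats::rnorm(length(ids), 0, 1.2))
  base <- numeric(length(ids))
  for (ph in unique(lineage$phylum)) {
    idx <- which(lineage$phylum == ph)
    base[idx] <- w[idx] / sum(w[idx]) * mass[idx][1]
  }
  base <- base / sum(base)
  k <- length(config$enterotype_proportions)
  means <- lapply(seq_len(k), function(e) {
    m <- base
    boost_idx <- which(lineage$genus == config$dominant_genera[e])
    m[boost_idx] <- m[boost_idx] * config$dominant_boost
    m / sum(m)
  })
  n <- config$n_samples
  sample_id <- sprintf("S%03d", seq_len(n))
  labels <- sample.int(k, n, replace = TRUE, prob = config$enterotype_proportions)
  latent <- stats::rnorm(n)
  depths <- sample(seq(config$depth_range[1], config$depth_range[2]), n, replace = TRUE)
  counts <- matrix(0, n, length(ids), dimnames = list(sample_id, ids))
  for (i in seq_len(n)) {
    alpha_i <- config$concentration * exp(config$latent_sd * latent[i]) * means[[labels[i]]]
    p <- dirichlet_row(alpha_i)
    counts[i, ] <- stats::rmultinom(1, depths[i], p)[, 1]
  }
  list(table = feature_table(counts, lineage),
       truth = tibble::tibble(sample_id = sample_id,
                              enterotype = as.integer(labels),
                              latent_diversity = latent))
}

food_group_names <- function() {
  c("potatoes", "vegetables", "fermented_vegetables", "seaweeds", "legumes",
    "fermented_legumes", "fruits", "nuts_seeds", "dairy", "refined_grains",
    "whole_grains", "other_cereals", "meats", "processed_meats",
    "fish_seafood", "eggs", "vegetable_oils", "other_fats",
    "sugar_confectionery", "cakes_sweets", "coffee", "tea",
    "nonalcoholic_beverages", "pizza_burgers", "salty_snacks")
}

default_pattern_weights <- function(groups) {
  w <- stats::setNames(numeric(length(groups)), groups)
  plant <- c(fermented_legumes = 1, vegetables = 0.9, potatoes = 0.8,
             seaweeds = 0.7, nuts_seeds = 0.6, tea = 0.5,
             nonalcoholic_beverages = -0.8)
  w[intersect(names(plant), groups)] <- plant[intersect(names(plant), groups)]
  w
}

#' Generate intake and covariate tables with a planted dietary pattern
#'
#' Total energy and each food group are log-normal; every food carries a slope
#' on log energy (so the energy-residual method has real structure to remove),
#' and the pattern foods additionally carry `diet_effect` times their planted
#' weight times the sample's latent diversity. Covariates are independent of
#' diet except a planted sex -> alcohol effect, the confounding fixture for
#' partial-correlation tests.
#'
#' @param config A [study_config()].
#' @param truth Ground-truth tibble from [generate_counts()].
#' @return List with `diet` (tibble: `sample_id`, `total_energy`, `alcohol`,
#'   one column per food group, g/day), `covariates` (tibble: `sample_id`,
#'   `sex`, `age`, `bmi`, `supplement`, `activity`, `smoking`, `batch`) and
#'   `pattern_weights` (named numeric, the planted direction).
#' @export
generate_diet <- function(config, truth) {
  stopifnot(inherits(config, "study_config"), is.data.frame(truth))
  set.seed(substream_seed(config$seed, "diet"))
  n <- nrow(truth)
  groups <- food_group_names()
  if (config$n_food_groups != length(groups)) {
    groups <- c(groups, sprintf("food_%02d", seq_len(max(0, config$n_food_groups - length(groups)))))
    groups <- groups[seq_len(config$n_food_groups)]
  }
  weights <- config$pattern_weights
  if (is.null(weights)) weights <- default_pattern_weights(groups)
  stopifnot(length(weights) == length(groups))
  names(weights) <- groups
  log_energy <- stats::rnorm(n, log(2100), 0.20)
  mu <- stats::runif(length(groups), log(5), log(250))
  slope <- stats::runif(length(groups), 0.3, 0.9)
  noise_sd <- 0.45
  z <- truth$latent_diversity
  intakes <- sapply(seq_along(groups), function(g) {
    exp(mu[g] + slope[g] * (log_energy - log(2100)) +
          config$diet_effect * weights[g] * 0.35 * z +
          stats::rnorm(n, 0, noise_sd))
  })
  colnames(intakes) <- groups
  # covariates (independent of diet except sex -> alcohol)
  sex <- ifelse(stats::runif(n) < 0.49, "M", "F")
  alcohol <- exp(log(6) + 0.9 * (sex == "M") + stats::rnorm(n, 0, 0.8))
  covariates <- tibble::tibble(
    sample_id = truth$sample_id,
    sex = sex,
    age = round(stats::runif(n, 18, 58)),
    bmi = pmin(pmax(stats::rnorm(n, 22.9, 2.4), 18.5), 29.9),
    supplement = ifelse(stats::runif(n) < 0.30, "yes", "no"),
    activity = ifelse(stats::runif(n) < 0.50, "yes", "no"),
    smoking = ifelse(stats::runif(n) < 0.35, "ever", "never"),
    batch = sprintf("b%d", sample.int(8, n, replace = TRUE))
  )
  diet <- tibble::as_tibble(as.data.frame(intakes))
  diet <- dplyr::bind_cols(
    tibble::tibble(sample_id = truth$sample_id,
                   total_energy = exp(log_energy),
                   alcohol = alcohol),
    diet
  )
  list(diet = diet, covariates = covariates, pattern_weights = weights)
}

#' Simulate a complete synthetic study
#'
#' Runs [generate_tree()], [generate_counts()] and [generate_diet()] under
#' independent sub-streams of `config$seed` and assembles the full ground
#' truth.
#'
#' @param config A [study_config()].
#' @return List of class `synthetic_study` with elements `config`, `tree`,
#'   `table`, `diet`, `covariates` and `truth` (the truth carries the planted
#'   `pattern_weights` as an attribute and column metadata).
#' @export
simulate_study <- function(config = study_config()) {
  tree <- generate_tree(config$n_taxa, config$seed)
  cnt <- generate_counts(config, tree)
  dt <- generate_diet(config, cnt$truth)
  truth <- cnt$truth
  attr(truth, "pattern_weights") <- dt$pattern_weights
  structure(list(config = config, tree = tree, table = cnt$table,
                 diet = dt$diet, covariates = dt$covariates, truth = truth),
            class = "synthetic_study")
}

#' Write a synthetic study to disk in the pipeline's standard formats
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of the file paths written (feature-table
#'   TSV, Newick tree, diet CSV, covariate CSV, ground-truth JSON).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    feature_table = file.path(dir, "feature_table.tsv"),
    tree = file.path(dir, "tree.nwk"),
    diet = file.path(dir, "diet.csv"),
    covariates = file.path(dir, "covariates.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_feature_table(study$table, paths$feature_table)
  ape::write.tree(study$tree, paths$tree)
  readr::write_csv(study$diet, paths$diet)
  readr::write_csv(study$covariates, paths$covariates)
  jsonlite::write_json(list(
    enterotype = stats::setNames(as.list(study$truth$enterotype), study$truth$sample_id),
    latent_diversity = stats::setNames(as.list(study$truth$latent_diversity),
                                       study$truth$sample_id),
    pattern_weights = as.list(attr(study$truth, "pattern_weights"))
  ), paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
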