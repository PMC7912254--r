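#' Pipeline configuration
#'
#' Bundles every choice of the end-to-end analysis. Inputs are either the
#' four standard file paths or an inline [study_config()] for a synthetic
#' cohort. Defaults follow the canonical analysis: rarefaction to the cohort
#' minimum, phylum + genus screens, Shannon (log-transformed) as the RRR
#' response, three enterotypes on the first two principal coordinates, 0.3
#' loading threshold, and the seven standard covariates.
#'
#' @param feature_table,tree,diet,covariates Input file paths (ignored when
#'   `study` is given).
#' @param study Optional [study_config()]; the synthetic study is generated,
#'   written under `out_dir/inputs` and then read back like real data.
#' @param out_dir Output directory.
#' @param depth Rarefaction depth; `NULL` = minimum sample total.
#' @param ranks Taxonomic ranks for the composition screens.
#' @param response Alpha-diversity index for the RRR response
#'   (`"shannon"`, `"chao1"` or `"faith_pd"`).
#' @param beta_metrics Beta-diversity matrices to compute; enterotypes are
#'   derived for each.
#' @param k Enterotype count (default 3).
#' @param k_max,gap_b [choose_k()] candidate range and gap-reference count.
#' @param loading_threshold Main-contributor cutoff (default 0.3).
#' @param covariate_names Covariate columns used in every adjusted analysis.
#' @param n_perm PERMANOVA permutations.
#' @param seed Root seed; every stage derives a named sub-stream from it.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(feature_table = NULL, tree = NULL, diet = NULL,
                            covariates = NULL, study = NULL, out_dir,
                            depth = NULL,
                            ranks = c("phylum", "genus"),
                            response = c("shannon", "chao1", "faith_pd"),
                            beta_metrics = c("weighted_unifrac", "bray_curtis",
                                             "unweighted_unifrac"),
                            k = 3, k_max = 8, gap_b = 50,
                            loading_threshold = 0.3,
                            covariate_names = c("sex", "age", "bmi", "supplement",
                                                "activity", "smoking", "batch"),
                            n_perm = 999, seed = 1L) {
  response <- match.arg(response)
  beta_metrics <- match.arg(beta_metrics, several.ok = TRUE)
  if (is.null(study)) {
    paths <- c(feature_table, tree, diet, covariates)
    if (length(paths) != 4) stop("provide all four input paths or a study config", call. = FALSE)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) stop("input path(s) not found: ",
                                  paste(missing, collapse = ", "), call. = FALSE)
  } else {
    stopifnot(inherits(study, "study_config"))
  }
  if (loading_threshold <= 0 || loading_threshold > 1) {
    stop("loading_threshold must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(k >= 1, is.null(depth) || depth >= 1)
  structure(list(feature_table = feature_table, tree = tree, diet = diet,
                 covariates = covariates, study = study, out_dir = out_dir,
                 depth = depth, ranks = ranks, response = response,
                 beta_metrics = beta_metrics, k = k, k_max = k_max,
                 gap_b = gap_b, loading_threshold = loading_threshold,
                 covariate_names = covariate_names, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_tidy <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  path
}

#' Run the full diet-microbiome analysis
#'
#' Executes ingest -> rarefaction -> per-rank aggregation / zero replacement /
#' clr -> alpha and beta diversity -> dietary energy adjustment -> the
#' phylum-level diet screen -> the RRR dietary pattern with its genus screen
#' -> enterotypes (per beta metric) with covariate-adjusted diet contrasts ->
#' PERMANOVA of covariates against beta diversity. Every stage writes a TSV
#' under `out_dir` and a provenance record (parameters, seeds, input
#' checksums, package version) is written at the end.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory results (`alpha`, `beta`,
#'   `pattern`, `contributors`, `pattern_screen`, `phylum_screen`,
#'   `enterotypes`, `contrasts`, `permanova`) and `paths` (every file
#'   written).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  paths <- list()

  # -- ingest -----------------------------------------------------------
  say("stage: ingest")
  if (!is.null(config$study)) {
    in_paths <- write_study(simulate_study(config$study), file.path(out_dir, "inputs"))
  } else {
    in_paths <- list(feature_table = config$feature_table, tree = config$tree,
                     diet = config$diet, covariates = config$covariates)
  }
  ft <- read_feature_table(in_paths$feature_table)
  tree <- read_tree(in_paths$tree)
  diet <- read_diet(in_paths$diet)
  covariates <- read_covariates(in_paths$covariates)
  missing_cov <- setdiff(config$covariate_names, names(covariates))
  if (length(missing_cov) > 0) {
    stop("join-error at screen stage: covariate column(s) absent: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  aligned <- align_samples(table = ft, diet = diet, covariates = covariates)
  ft <- aligned$table; diet <- aligned$diet; covariates <- aligned$covariates
  cov_use <- covariates[, c("sample_id", config$covariate_names), drop = FALSE]

  # -- rarefaction ------------------------------------------------------
  say("stage: rarefy")
  rare <- rarefy(ft, depth = config$depth, seed = substream_seed(config$seed, "stage_rarefy"))
  if (length(attr(rare, "dropped")) > 0) {
    keep <- rownames(rare$counts)
    diet <- diet[match(keep, diet$sample_id), ]
    covariates <- covariates[match(keep, covariates$sample_id), ]
    cov_use <- covariates[, c("sample_id", config$covariate_names), drop = FALSE]
  }
  paths$rarefied <- write_tidy(
    tibble::as_tibble(cbind(sample_id = rownames(rare$counts),
                            as.data.frame(rare$counts))),
    file.path(out_dir, "rarefied_counts.tsv"))

  # -- compositions per rank -------------------------------------------
  say("stage: compositions")
  comps <- list()
  for (rank in config$ranks) {
    agg <- aggregate_taxa(rare, rank)
    cm <- clr_transform(replace_zeros(to_proportions(agg)))
    comps[[rank]] <- list(table = agg, clr = cm,
                          proportions = to_proportions(agg))
    paths[[paste0("clr_", rank)]] <- write_tidy(
      tibble::as_tibble(cbind(sample_id = rownames(cm$values),
                              as.data.frame(cm$values))),
      file.path(out_dir, paste0("clr_", rank, ".tsv")))
  }

  # -- alpha diversity --------------------------------------------------
  say("stage: alpha diversity")
  alpha <- alpha_diversity(rare, tree)
  paths$alpha <- write_tidy(alpha, file.path(out_dir, "alpha_diversity.tsv"))

  # -- beta diversity ---------------------------------------------------
  say("stage: beta diversity")
  beta <- list()
  for (metric in config$beta_metrics) {
    beta[[metric]] <- beta_diversity(rare, metric, tree)
    paths[[paste0("beta_", metric)]] <- write_distance_matrix(
      beta[[metric]], file.path(out_dir, paste0("beta_", metric, ".tsv")))
  }

  # -- dietary adjustment ----------------------------------------------
  say("stage: diet adjustment")
  adj_diet <- adjust_diet(diet)
  paths$adjusted_diet <- write_tidy(adj_diet, file.path(out_dir, "adjusted_diet.tsv"))
  food_cols <- setdiff(names(adj_diet), c("sample_id", "alcohol"))

  # -- phylum-level diet screen (heatmap analogue) ---------------------
  say("stage: phylum screen")
  phylum_screen <- NULL
  if ("phylum" %in% names(comps)) {
    clr_phy <- comps$phylum$clr
    left <- clr_phy$values
    if (all(c("Firmicutes", "Bacteroidetes") %in% colnames(left))) {
      left <- cbind(left, fb_ratio = clr_log_ratio(clr_phy, "Firmicutes", "Bacteroidetes"))
    }
    phylum_screen <- correlation_screen(left, adj_diet[, food_cols], cov_use)
    paths$phylum_screen <- write_tidy(phylum_screen,
                                      file.path(out_dir, "phylum_diet_screen.tsv"))
  }

  # -- RRR dietary pattern ---------------------------------------------
  say("stage: dietary pattern")
  y <- log(alpha[[config$response]])
  pattern <- fit_rrr(adj_diet[, c("sample_id", food_cols)], y,
                     response_name = paste0("log_", config$response))
  contributors <- main_contributors(pattern, config$loading_threshold)
  paths$pattern_loadings <- write_tidy(tidy(pattern),
                                       file.path(out_dir, "pattern_loadings.tsv"))
  paths$pattern_scores <- write_tidy(pattern$scores,
                                     file.path(out_dir, "pattern_scores.tsv"))
  paths$pattern_contributors <- write_tidy(contributors,
                                           file.path(out_dir, "pattern_contributors.tsv"))
  pattern_screen <- NULL
  if ("genus" %in% names(comps)) {
    genus_tbl <- comps$genus$table
    scope <- stats::setNames(genus_tbl$lineage$phylum, genus_tbl$lineage$genus)
    pattern_screen <- pattern_taxa_screen(pattern$scores, comps$genus$clr,
                                          cov_use, fdr_scope = scope)
    paths$pattern_screen <- write_tidy(pattern_screen,
                                       file.path(out_dir, "pattern_genus_screen.tsv"))
  }

  # -- enterotypes ------------------------------------------------------
  say("stage: enterotypes")
  genus_prop <- comps$genus$proportions
  enterotypes <- list()
  contrasts <- list()
  for (metric in config$beta_metrics) {
    fit <- find_enterotypes(beta[[metric]], genus_prop, k = config$k,
                            k_max = config$k_max, B = config$gap_b,
                            seed = substream_seed(config$seed, paste0("et_", metric)))
    enterotypes[[metric]] <- fit
    paths[[paste0("enterotype_", metric)]] <- write_tidy(
      tidy(fit), file.path(out_dir, paste0("enterotype_", metric, ".tsv")))
    if (!is.null(fit$diagnostics)) {
      paths[[paste0("kdiag_", metric)]] <- write_tidy(
        tibble::as_tibble(fit$diagnostics),
        file.path(out_dir, paste0("k_diagnostics_", metric, ".tsv")))
    }
    vars <- dplyr::left_join(pattern$scores, adj_diet, by = "sample_id") |>
      dplyr::rename(hiadp_score = "score")
    contrasts[[metric]] <- enterotype_contrasts(fit, vars, cov_use)
    paths[[paste0("contrasts_", metric)]] <- write_tidy(
      contrasts[[metric]], file.path(out_dir, paste0("enterotype_contrasts_", metric, ".tsv")))
  }

  # -- PERMANOVA of covariates vs beta diversity -----------------------
  say("stage: permanova")
  perm <- purrr::map_dfr(config$covariate_names, function(cv) {
    val <- covariates[[cv]]
    names(val) <- covariates$sample_id
    if (is.character(val) &&
        (length(unique(val)) > min(8, length(val) / 2) || any(table(val) < 2))) {
      return(NULL)  # too sparse for a grouped PERMANOVA
    }
    dplyr::bind_cols(tibble::tibble(covariate = cv),
                     permanova(beta[[config$beta_metrics[1]]], val,
                               n_perm = config$n_perm,
                               seed = substream_seed(config$seed, paste0("perm_", cv))))
  })
  paths$permanova <- write_tidy(perm, file.path(out_dir, "permanova.tsv"))

  # -- provenance -------------------------------------------------------
  say("stage: provenance")
  prov <- list(
    package_version = as.character(utils::packageVersion("gutdiet")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("study", "out_dir"))],
    rarefaction_depth = attr(rare, "depth"),
    dropped_samples = attr(rare, "dropped"),
    input_checksums = as.list(stats::setNames(unname(tools::md5sum(unlist(in_paths))),
                                              names(in_paths))),
    outputs = basename(unname(unlist(paths)))
  )
  prov$parameters$study <- NULL
  paths$provenance <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)

  invisible(list(alpha = alpha, beta = beta, pattern = pattern,
                 contributors = contributors, pattern_screen = pattern_screen,
                 phylum_screen = phylum_screen, enterotypes = enterotypes,
                 contrasts = contrasts, permanova = perm, rarefied = rare,
                 adjusted_diet = adj_diet, paths = paths))
}
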