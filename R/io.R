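#' Parse Greengenes-style lineage strings
#'
#' `"p__Firmicutes;c__;o__;f__;g__Lactobacillus"` parses to a tibble row with
#' `phylum = "Firmicutes"`, `genus = "Lactobacillus"` and `"unclassified"` for
#' the empty ranks. Rank prefixes are `p__`, `c__`, `o__`, `f__`, `g__`;
#' missing ranks are treated as unassigned.
#'
#' @param x Character vector of semicolon-delimited lineage strings.
#' @return Tibble with columns `phylum`, `class`, `order`, `family`, `genus`.
#' @export
parse_lineage <- function(x) {
  prefixes <- c(phylum = "p", class = "c", order = "o", family = "f", genus = "g")
  rows <- lapply(x, function(s) {
    parts <- stringr::str_split_1(s, ";")
    parts <- stringr::str_trim(parts)
    out <- stats::setNames(rep("unclassified", 5), names(prefixes))
    for (p in parts) {
      m <- stringr::str_match(p, "^([a-z])__(.*)$")
      if (is.na(m[1, 1])) next
      rank <- names(prefixes)[match(m[1, 2], prefixes)]
      if (!is.na(rank) && nzchar(m[1, 3])) out[rank] <- m[1, 3]
    }
    out
  })
  tibble::as_tibble(do.call(rbind, rows))
}

format_lineage <- function(lineage) {
  prefixes <- c(phylum = "p", class = "c", order = "o", family = "f", genus = "g")
  apply(as.data.frame(lineage[, names(prefixes)]), 1, function(r) {
    paste(sprintf("%s__%s", prefixes, ifelse(r == "unclassified", "", r)),
          collapse = ";")
  })
}

#' Read a feature table from TSV
#'
#' Canonical orientation: rows = taxa, columns = samples, first column
#' `taxon_id`, last column `lineage` with Greengenes-style rank prefixes.
#' `samples_as_rows = TRUE` flips the convention (no lineage column expected
#' then unless present under `lineage`).
#'
#' @param path TSV file path.
#' @param samples_as_rows Set `TRUE` if the file stores samples as rows.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, samples_as_rows = FALSE) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (samples_as_rows) {
    ids <- df[[1]]
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- ids
    lineage <- NULL
  } else {
    if (names(df)[1] != "taxon_id") stop("format-error: first column must be `taxon_id`", call. = FALSE)
    lineage_str <- NULL
    if ("lineage" %in% names(df)) {
      lineage_str <- df$lineage
      df$lineage <- NULL
    }
    taxa <- df$taxon_id
    if (anyDuplicated(taxa)) {
      stop("format-error: duplicate taxon id ", taxa[duplicated(taxa)][1], call. = FALSE)
    }
    mat <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(mat) <- taxa
    lineage <- if (!is.null(lineage_str)) {
      dplyr::bind_cols(tibble::tibble(taxon_id = taxa), parse_lineage(lineage_str))
    }
  }
  if (anyDuplicated(rownames(mat))) {
    stop("format-error: duplicate sample id ", rownames(mat)[duplicated(rownames(mat))][1],
         call. = FALSE)
  }
  if (!is.numeric(mat)) stop("format-error: non-numeric counts", call. = FALSE)
  bad <- which(mat < 0 | abs(mat - round(mat)) > 1e-9, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("format-error: invalid count at sample '%s', taxon '%s'",
                 rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]), call. = FALSE)
  }
  feature_table(mat, lineage)
}

#' Write a feature table to TSV (rows = taxa, columns = samples)
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- tibble::as_tibble(t(table$counts))
  df <- dplyr::bind_cols(tibble::tibble(taxon_id = colnames(table$counts)), df)
  df$lineage <- format_lineage(table$lineage)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' @param path Newick file path.
#' @return An `ape::phylo` tree, validated: rooted, unique leaf names, every
#'   edge carries a non-negative branch length.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("format-error: could not parse Newick file", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("format-error: tree must be rooted", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) stop("format-error: duplicate leaf names", call. = FALSE)
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    stop("format-error: missing branch length", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("format-error: negative branch length", call. = FALSE)
  tree
}

#' Read the diet table (CSV)
#'
#' Expected columns: `sample_id`, `total_energy` (kcal/day, positive),
#' `alcohol` (g/day, non-negative), then one non-negative g/day column per
#' food group.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_diet <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "total_energy", "alcohol")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("format-error: diet table missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) stop("format-error: duplicate sample id", call. = FALSE)
  if (any(df$total_energy <= 0)) stop("format-error: non-positive total energy", call. = FALSE)
  foods <- setdiff(names(df), need)
  vals <- as.matrix(df[, c("alcohol", foods)])
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("format-error: negative intake at sample '%s', column '%s'",
                 df$sample_id[bad[1]], colnames(vals)[bad[2]]), call. = FALSE)
  }
  tibble::as_tibble(df)
}

covariate_schema <- function() {
  list(sex = c("M", "F"), supplement = c("yes", "no"), activity = c("yes", "no"),
       smoking = c("ever", "never"))
}

#' Read the covariate table (CSV)
#'
#' Expected columns: `sample_id`, `sex` (M/F), `age` (years), `bmi` (kg/m2),
#' `supplement` (yes/no), `activity` (yes/no), `smoking` (ever/never),
#' `batch` (free categorical). Unknown categorical levels are a format error.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_covariates <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "sex", "age", "bmi", "supplement", "activity", "smoking", "batch")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("format-error: covariate table missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) stop("format-error: duplicate sample id", call. = FALSE)
  for (col in names(covariate_schema())) {
    levels_ok <- covariate_schema()[[col]]
    bad <- setdiff(unique(df[[col]]), levels_ok)
    if (length(bad) > 0) {
      stop(sprintf("format-error: column '%s' has level '%s' outside {%s}",
                   col, bad[1], paste(levels_ok, collapse = ", ")), call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

#' Write / read a distance matrix as TSV
#'
#' @param dm Symmetric distance matrix with sample-id dimnames.
#' @param path File path.
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns the validated matrix.
#' @export
write_distance_matrix <- function(dm, path) {
  dm <- as_distance_matrix(dm)
  df <- tibble::as_tibble(dm)
  df <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(dm)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- df$sample_id
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- ids
  if (!identical(colnames(mat), ids)) {
    stop("format-error: row and column sample ids differ", call. = FALSE)
  }
  as_distance_matrix(mat)
}

#' Read a flat key:value study or pipeline configuration (YAML or JSON)
#'
#' @param path `.yaml`/`.yml` or `.json` file with keys matching
#'   [study_config()] arguments.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("format-error: unknown config key(s) ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(study_config, cfg)
}

#' Validate a directory of pipeline inputs and print a schema report
#'
#' Checks that the four standard inputs parse, that taxa of the feature table
#' appear in the tree, and reports the sample overlap across tables.
#'
#' @param feature_table,tree,diet,covariates File paths.
#' @param quiet Suppress the printed report.
#' @return Invisibly, a list with the parsed objects and an `issues` character
#'   vector (empty when everything is consistent).
#' @export
validate_inputs <- function(feature_table, tree, diet, covariates, quiet = FALSE) {
  ft <- read_feature_table(feature_table)
  tr <- read_tree(tree)
  dt <- read_diet(diet)
  cv <- read_covariates(covariates)
  issues <- character()
  missing_tips <- setdiff(colnames(ft$counts), tr$tip.label)
  if (length(missing_tips) > 0) {
    issues <- c(issues, sprintf("%d taxa absent from the tree (e.g. %s)",
                                length(missing_tips), missing_tips[1]))
  }
  ids <- list(feature_table = rownames(ft$counts), diet = dt$sample_id,
              covariates = cv$sample_id)
  common <- Reduce(intersect, ids)
  for (nm in names(ids)) {
    extra <- length(setdiff(ids[[nm]], common))
    if (extra > 0) issues <- c(issues, sprintf("%s: %d sample(s) outside the common set", nm, extra))
  }
  if (!quiet) {
    cat(sprintf("feature table: %d samples x %d taxa\n", nrow(ft$counts), ncol(ft$counts)))
    cat(sprintf("tree: %d leaves\n", length(tr$tip.label)))
    cat(sprintf("diet: %d samples x %d food groups\n", nrow(dt),
                ncol(dt) - 3L))
    cat(sprintf("covariates: %d samples\n", nrow(cv)))
    cat(sprintf("common samples: %d\n", length(common)))
    if (length(issues) > 0) cat("issues:\n", paste(" -", issues, collapse = "\n"), "\n")
    else cat("no issues found\n")
  }
  invisible(list(feature_table = ft, tree = tr, diet = dt, covariates = cv,
                 issues = issues))
}
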