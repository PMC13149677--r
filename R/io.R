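# Delimited-text readers and writers (TSV canonical, comma sniffed), study
# serialization, and the end-to-end pipeline runner.

.read_delim_auto <- function(path) {
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Read a wide feature abundance matrix
#'
#' First column feature ids, header row sample ids. Empty cells are read as
#' zero and counted in the `n_missing` attribute; non-numeric cells and
#' duplicate labels are errors.
#'
#' @param path TSV or CSV file path.
#' @return Numeric matrix (features x samples) with an `n_missing`
#'   attribute.
#' @export
read_feature_matrix <- function(path) {
  raw <- .read_delim_auto(path)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature ids in abundance matrix", call. = FALSE)
  }
  if (anyDuplicated(names(raw)[-1])) {
    stop("duplicate sample ids in abundance matrix", call. = FALSE)
  }
  vals <- raw[, -1, drop = FALSE]
  n_missing <- 0L
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (is.character(col)) {
      empty <- is.na(col) | !nzchar(trimws(col))
      num <- suppressWarnings(as.numeric(col))
      bad <- is.na(num) & !empty
      if (any(bad)) {
        stop(sprintf("non-numeric cell in column '%s': '%s'",
                     names(vals)[[j]], col[bad][[1]]), call. = FALSE)
      }
      num[empty] <- 0
      n_missing <- n_missing + sum(empty)
      vals[[j]] <- num
    } else {
      empty <- is.na(col)
      n_missing <- n_missing + sum(empty)
      col[empty] <- 0
      vals[[j]] <- col
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (n_missing > 0) {
    message(sprintf("read_feature_matrix: %d empty cell(s) set to 0",
                    n_missing))
  }
  attr(m, "n_missing") <- n_missing
  m
}

#' Read a feature annotation table
#'
#' Columns: `feature_id`, `annotation_level`, `formula`, and optionally
#' `inchikey`, `compound_name`, `superclass`.
#'
#' @param path TSV or CSV file path.
#' @return A validated feature tibble.
#' @export
read_annotation_table <- function(path) {
  out <- .read_delim_auto(path)
  .check_feature_table(out)
  out
}

#' Read a sample metadata table
#'
#' Columns: `sample_id`, `food_name`, `organism_name`, `foodon_l1`,
#' optionally `foodon_l2`.
#'
#' @param path TSV or CSV file path.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  out <- .read_delim_auto(path)
  required <- c("sample_id", "food_name", "organism_name", "foodon_l1")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    stop(sprintf("metadata is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample ids in metadata", call. = FALSE)
  }
  out
}

#' Write a synthetic study to a directory
#'
#' Writes `abundance.tsv` (wide matrix), `features.tsv`, `metadata.tsv`,
#' one reference table per source under `references/`, and
#' `ground_truth.json`. Output is deterministic for a given study object.
#'
#' @param study A `synthetic_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(file.path(dir, "references"), recursive = TRUE,
             showWarnings = FALSE)
  wide <- tibble::as_tibble(study$abundance, rownames = "feature_id")
  readr::write_tsv(wide, file.path(dir, "abundance.tsv"))
  readr::write_tsv(study$features, file.path(dir, "features.tsv"))
  readr::write_tsv(study$metadata, file.path(dir, "metadata.tsv"))
  for (s in names(study$references)) {
    readr::write_tsv(study$references[[s]],
                     file.path(dir, "references", paste0(s, ".tsv")))
  }
  gt <- study$ground_truth
  gt$novel_pairs <- as.list(gt$novel_pairs)
  gt$decoy_pairs <- as.list(gt$decoy_pairs)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load reference tables from a study directory into an index
#'
#' @param dir Directory containing `references/<source>.tsv`.
#' @param keep_categories Optional therapeutic-category whitelist applied
#'   with [select_therapeutic_categories()].
#' @return A `reference_index`.
#' @export
load_reference_dir <- function(dir, keep_categories = NULL) {
  refdir <- file.path(dir, "references")
  paths <- list.files(refdir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(paths) == 0) {
    stop(sprintf("no reference tables under %s", refdir), call. = FALSE)
  }
  tables <- lapply(paths, function(p) {
    src <- sub("\\.tsv$", "", basename(p))
    read_reference_table(p, source_id = src)
  })
  index <- build_reference_index(tables)
  if (!is.null(keep_categories)) {
    index <- select_therapeutic_categories(index, keep_categories)
  }
  index
}

#' Run the full screening pipeline
#'
#' Executes the two-branch workflow on an in-memory study or a study
#' directory written by [write_study()]: InChIKey matching of
#' structure-annotated features, formula-level xenobiotic classification,
#' fluorine prioritization, DBE and heteroatom profiling, the
#' novel-producer screen, and FoodOn level-1 aggregation of the matched
#' subsets. A run manifest records stage row counts; reruns on identical
#' inputs are identical.
#'
#' @param study A `synthetic_study`, or a directory path containing
#'   `abundance.tsv`, `features.tsv`, `metadata.tsv` and `references/`.
#' @param prevalence_threshold,prevalence_population,detect_min Passed to
#'   [screen_novel_producers()].
#' @param aggregation Aggregation mode for the group matrix (`"mean"` or
#'   `"sum"`; both are reported in figures of this kind, so the choice is
#'   explicit with no default bias -- `"mean"` here).
#' @return A list of class `screen_report`: `matches`, `calls`, `summary`,
#'   `unclassifiable`, `fluorinated`, `dbe_histogram`,
#'   `heteroatom_summary`, `novel_pairs`, `agg_foodon_l1`, `manifest`.
#' @export
run_pipeline <- function(study,
                         prevalence_threshold = 0.10,
                         prevalence_population = "plant",
                         detect_min = 0,
                         aggregation = "mean") {
  if (is.character(study)) {
    dir <- study
    for (f in c("abundance.tsv", "features.tsv", "metadata.tsv")) {
      if (!file.exists(file.path(dir, f))) {
        stop(sprintf("input validation: missing %s under %s", f, dir),
             call. = FALSE)
      }
    }
    abundance <- read_feature_matrix(file.path(dir, "abundance.tsv"))
    features <- read_annotation_table(file.path(dir, "features.tsv"))
    metadata <- read_sample_metadata(file.path(dir, "metadata.tsv"))
    index <- load_reference_dir(dir)
  } else {
    stopifnot(inherits(study, "synthetic_study"))
    abundance <- study$abundance
    features <- study$features
    metadata <- study$metadata
    index <- build_reference_index(lapply(names(study$references),
                                          function(s) {
      as_reference_table(study$references[[s]], s)
    }))
  }

  matches <- match_structures(features, index)
  cls <- classify_features(features, index)
  fl <- filter_fluorinated(cls$calls)
  hist <- dbe_histogram(cls$calls)
  het <- heteroatom_summary(cls$calls)
  long <- to_long(abundance)
  novel <- screen_novel_producers(
    features, long, metadata, index,
    prevalence_threshold = prevalence_threshold,
    prevalence_population = prevalence_population,
    detect_min = detect_min
  )
  agg <- aggregate_by_group(
    long, metadata, group_by = "foodon_l1",
    feature_sets = list(
      drug = matches$feature_id[matches$matched_drug],
      fcc = matches$feature_id[matches$matched_fcc],
      agrochem = matches$feature_id[matches$matched_agrochem]
    ),
    aggregation = aggregation, transform = "log10p1"
  )

  manifest <- list(
    n_features = nrow(features),
    n_samples = nrow(metadata),
    n_structure = cls$summary$n_structure,
    n_formula_only = cls$summary$n_formula_only,
    n_matched_drug = sum(matches$matched_drug),
    n_matched_fcc = sum(matches$matched_fcc),
    n_matched_agrochem = sum(matches$matched_agrochem),
    n_np_match = cls$summary$n_np_match,
    n_xenobiotic = cls$summary$n_xenobiotic,
    n_unclassifiable = cls$summary$n_unclassifiable,
    n_fluorinated = nrow(fl),
    n_novel_pairs = nrow(novel),
    pct_xenobiotic_of_total = cls$summary$pct_xenobiotic_of_total
  )
  structure(list(matches = matches, calls = cls$calls,
                 summary = cls$summary,
                 unclassifiable = cls$unclassifiable,
                 fluorinated = fl, dbe_histogram = hist,
                 heteroatom_summary = het, novel_pairs = novel,
                 agg_foodon_l1 = agg, manifest = manifest),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  m <- x$manifest
  cat(sprintf("  %d features x %d samples\n", m$n_features, m$n_samples))
  cat(sprintf("  matched: drug %d, food-contact %d, agrochemical %d\n",
              m$n_matched_drug, m$n_matched_fcc, m$n_matched_agrochem))
  cat(sprintf("  xenobiotics: %d (%.1f%% of all features), %d fluorinated\n",
              m$n_xenobiotic, m$pct_xenobiotic_of_total, m$n_fluorinated))
  cat(sprintf("  novel compound-genus pairs: %d\n", m$n_novel_pairs))
  invisible(x)
}
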