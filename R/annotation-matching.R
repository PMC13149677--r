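# InChIKey matching of structure-annotated features against the drug-like
# references. Only features annotated at the structure level are eligible;
# formula-only features keep all-false flags regardless of their formula
# (they follow the formula-screen branch instead).

.check_feature_table <- function(features) {
  required <- c("feature_id", "annotation_level", "formula")
  missing <- setdiff(required, names(features))
  if (length(missing) > 0) {
    stop(sprintf("feature table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature_id in feature table", call. = FALSE)
  }
  bad <- !features$annotation_level %in% c("structure", "formula_only")
  if (any(bad)) {
    stop(sprintf("unknown annotation_level: %s",
                 paste(unique(features$annotation_level[bad]), collapse = ", ")),
         call. = FALSE)
  }
  if (!"inchikey" %in% names(features)) {
    if (any(features$annotation_level == "structure")) {
      stop("structure-annotated features require an inchikey column",
           call. = FALSE)
    }
    features$inchikey <- NA_character_
  } else if (any(features$annotation_level == "structure" &
                 is.na(features$inchikey))) {
    stop("structure-annotated feature without an InChIKey", call. = FALSE)
  }
  invisible(features)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match structure-annotated features to drug-like references by InChIKey
#'
#' Exact, case-sensitive equality of the full 27-character InChIKey against
#' each drug-like source's key set. `block1` mode relaxes matching to the
#' first (skeleton) block only, conflating stereoisomers and protonation
#' states; it is off by default. Matched pharmaceutical compounds also
#' receive their therapeutic categories from the index's category map.
#'
#' @param features Feature tibble with columns `feature_id`,
#'   `annotation_level` (`"structure"` or `"formula_only"`), `formula`, and
#'   `inchikey` (required for structure-level rows).
#' @param index A `reference_index`.
#' @param match_mode `"full"` (default) or `"block1"`.
#' @return A tibble with one row per feature, in the order of first
#'   appearance sorted by `feature_id`: `feature_id`, `matched_drug`,
#'   `matched_fcc`, `matched_agrochem`, `categories` (semicolon-joined,
#'   sorted; empty string when none).
#' @export
match_structures <- function(features, index, match_mode = c("full", "block1")) {
  match_mode <- match.arg(match_mode)
  features <- .check_feature_table(features)
  stopifnot(inherits(index, "reference_index"))

  key_of <- function(x) {
    if (match_mode == "block1") substr(x, 1, 14) else x
  }
  sets <- lapply(index$inchikey_sets[.DRUG_LIKE_SOURCES], key_of)
  cat_keys <- key_of(names(index$category_map))

  eligible <- features$annotation_level == "structure"
  keys <- ifelse(eligible, key_of(features$inchikey), NA_character_)

  matched_drug <- !is.na(keys) & keys %in% sets$drugbank
  matched_fcc <- !is.na(keys) & keys %in% sets$fccdb
  matched_agrochem <- !is.na(keys) & keys %in% sets$agrochem

  categories <- vapply(seq_along(keys), function(i) {
    if (!matched_drug[[i]]) return("")
    hits <- which(cat_keys == keys[[i]])
    if (length(hits) == 0) return("")
    paste(sort(unique(unlist(index$category_map[hits]))), collapse = ";")
  }, character(1))

  out <- tibble::tibble(
    feature_id = features$feature_id,
    matched_drug = matched_drug,
    matched_fcc = matched_fcc,
    matched_agrochem = matched_agrochem,
    categories = categories
  )
  out[order(out$feature_id), , drop = FALSE]
}
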