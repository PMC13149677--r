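# Taxonomy-aware novel-producer screen.
#
# For structure-annotated compounds matched to pharmaceutical references,
# each detection in a food sample is compared against the genus-level
# occurrence records aggregated over the natural-product databases: a
# (compound, genus) pair is a candidate novel producer when the sample's
# organism genus is absent from all recorded producers of that compound.
# Ubiquitous compounds are removed first by a prevalence filter.

#' Extract the genus from an organism binomial
#'
#' First whitespace-delimited token, capitalized. A single lowercase token
#' that does not look like a capitalized Latin genus (e.g. `"unknown"`), or
#' an empty string, yields `NA`. Subspecific tokens after the first are
#' ignored.
#'
#' @param organism_name Character vector of organism name strings.
#' @return Character vector of capitalized genus names, `NA` where no genus
#'   could be extracted.
#' @examples
#' extract_genus(c("Daucus carota", "cirsium arvense", "unknown"))
#' @export
extract_genus <- function(organism_name) {
  vapply(organism_name, function(x) {
    if (is.na(x)) return(NA_character_)
    tokens <- strsplit(trimws(x), "[[:space:]]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == 0) return(NA_character_)
    first <- tokens[[1]]
    if (!grepl("^[A-Za-z][A-Za-z-]*$", first)) return(NA_character_)
    if (length(tokens) == 1 && !grepl("^[A-Z][a-z-]+$", first)) {
      # bare non-binomial strings like "unknown" carry no genus
      return(NA_character_)
    }
    .normalize_genus(first)
  }, character(1), USE.NAMES = FALSE)
}

.abundance_to_long <- function(abundance) {
  if (is.matrix(abundance)) {
    to_long(abundance)
  } else if (is.data.frame(abundance) &&
             all(c("feature_id", "sample_id", "intensity") %in%
                 names(abundance))) {
    abundance
  } else {
    stop("abundance must be a features x samples matrix or a long tibble ",
         "with feature_id, sample_id, intensity", call. = FALSE)
  }
}

.check_sample_alignment <- function(long, metadata) {
  missing <- setdiff(unique(long$sample_id), metadata$sample_id)
  if (length(missing) > 0) {
    stop(sprintf("sample id(s) in abundance but not in metadata: %s",
                 paste(utils::head(sort(missing), 10), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Screen for novel compound-genus producer pairs
#'
#' Restricts to structure-annotated compounds (by default, those matched to
#' the pharmaceutical reference), removes ubiquitous compounds whose
#' detection prevalence exceeds `prevalence_threshold` (strictly), and emits
#' one pair per (compound, genus) where the compound is detected in a sample
#' whose organism genus is absent from the compound's known producing
#' genera. Genus occurrence is looked up by InChIKey, with canonical-formula
#' fallback when no genus record exists under the key. Pairs are
#' deduplicated keeping the maximum-intensity detection.
#'
#' @param features Feature tibble (see [match_structures()]).
#' @param abundance Features x samples numeric matrix (dimnames required)
#'   or a long tibble from [to_long()].
#' @param metadata Sample metadata tibble with `sample_id`, `food_name`,
#'   `organism_name`, `foodon_l1`.
#' @param index A `reference_index` with genus occurrence records.
#' @param scope `"drug-matched"` (default; compounds matched by InChIKey to
#'   the pharmaceutical source) or `"all-structure"`.
#' @param prevalence_threshold Maximum allowed detection prevalence
#'   (default 0.10); compounds above it are excluded entirely.
#' @param prevalence_population Denominator population for prevalence:
#'   `"plant"` (default; samples with `foodon_l1 == "plant"`) or `"all"`.
#' @param detect_min Detection floor: a cell counts as a detection when its
#'   intensity is strictly greater than this value (default 0).
#' @return A tibble with columns `inchikey`, `compound_name`, `genus`,
#'   `best_sample`, `max_intensity`, `prevalence`, ordered by `inchikey`
#'   then `genus`.
#' @export
screen_novel_producers <- function(features, abundance, metadata, index,
                                   scope = c("drug-matched", "all-structure"),
                                   prevalence_threshold = 0.10,
                                   prevalence_population = c("plant", "all"),
                                   detect_min = 0) {
  scope <- match.arg(scope)
  prevalence_population <- match.arg(prevalence_population)
  features <- .check_feature_table(features)
  stopifnot(inherits(index, "reference_index"))
  long <- .abundance_to_long(abundance)
  .check_sample_alignment(long, metadata)

  str_features <- features[features$annotation_level == "structure", ,
                           drop = FALSE]
  if (scope == "drug-matched") {
    flags <- match_structures(features, index)
    drug_ids <- flags$feature_id[flags$matched_drug]
    str_features <- str_features[str_features$feature_id %in% drug_ids, ,
                                 drop = FALSE]
  }
  if (nrow(str_features) == 0) {
    return(tibble::tibble(inchikey = character(), compound_name = character(),
                          genus = character(), best_sample = character(),
                          max_intensity = numeric(), prevalence = numeric()))
  }

  pop_samples <- if (prevalence_population == "plant") {
    metadata$sample_id[metadata$foodon_l1 == "plant"]
  } else {
    metadata$sample_id
  }
  if (length(pop_samples) == 0) {
    stop("prevalence denominator population is empty", call. = FALSE)
  }

  genus_by_sample <- stats::setNames(extract_genus(metadata$organism_name),
                                     metadata$sample_id)

  det <- long[long$feature_id %in% str_features$feature_id &
                long$intensity > detect_min, , drop = FALSE]

  rows <- lapply(seq_len(nrow(str_features)), function(i) {
    fid <- str_features$feature_id[[i]]
    d <- det[det$feature_id == fid, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    prevalence <- sum(d$sample_id %in% pop_samples) / length(pop_samples)
    if (prevalence > prevalence_threshold) return(NULL)
    key <- str_features$inchikey[[i]]
    known <- known_genera(index, key)
    if (length(known) == 0) {
      known <- known_genera(index, canonical_formula(str_features$formula[[i]]))
    }
    gen <- unname(genus_by_sample[d$sample_id])
    novel <- !is.na(gen) & !(tolower(gen) %in% tolower(known))
    if (!any(novel)) return(NULL)
    d <- d[novel, , drop = FALSE]
    gen <- gen[novel]
    # dedupe to one row per genus, keeping max intensity (tie: smaller
    # sample id)
    ord <- order(gen, -d$intensity, d$sample_id)
    d <- d[ord, , drop = FALSE]
    gen <- gen[ord]
    first <- !duplicated(gen)
    nm <- if ("compound_name" %in% names(str_features)) {
      str_features$compound_name[[i]]
    } else NA_character_
    tibble::tibble(inchikey = key, compound_name = nm, genus = gen[first],
                   best_sample = d$sample_id[first],
                   max_intensity = d$intensity[first],
                   prevalence = prevalence)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(inchikey = character(), compound_name = character(),
                          genus = character(), best_sample = character(),
                          max_intensity = numeric(), prevalence = numeric()))
  }
  out[order(out$inchikey, out$genus), , drop = FALSE]
}

#' Rank producers (novel and known) of screened compounds by intensity
#'
#' For each compound appearing in the novel-pair table, merges every
#' detection of that compound into a single ranking ordered by decreasing
#' intensity (ties broken by sample id), flagging the samples whose genus is
#' absent from the compound's known producers.
#'
#' @param pairs Output of [screen_novel_producers()].
#' @param features Feature tibble (to map InChIKeys back to feature ids).
#' @param abundance Matrix or long tibble as in [screen_novel_producers()].
#' @param metadata Sample metadata tibble.
#' @param index A `reference_index`.
#' @param detect_min Detection floor (default 0).
#' @return A tibble with `inchikey`, `compound_name`, `rank`, `sample_id`,
#'   `food_name`, `genus`, `intensity`, `novel`.
#' @export
rank_producers <- function(pairs, features, abundance, metadata, index,
                           detect_min = 0) {
  features <- .check_feature_table(features)
  long <- .abundance_to_long(abundance)
  .check_sample_alignment(long, metadata)
  genus_by_sample <- stats::setNames(extract_genus(metadata$organism_name),
                                     metadata$sample_id)
  food_by_sample <- stats::setNames(metadata$food_name, metadata$sample_id)

  rows <- lapply(unique(pairs$inchikey), function(key) {
    feat <- features[!is.na(features$inchikey) & features$inchikey == key, ,
                     drop = FALSE]
    if (nrow(feat) == 0) return(NULL)
    known <- known_genera(index, key)
    if (length(known) == 0) {
      known <- known_genera(index, canonical_formula(feat$formula[[1]]))
    }
    d <- long[long$feature_id %in% feat$feature_id &
                long$intensity > detect_min, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    d <- d[order(-d$intensity, d$sample_id), , drop = FALSE]
    gen <- genus_by_sample[d$sample_id]
    tibble::tibble(
      inchikey = key,
      compound_name = pairs$compound_name[match(key, pairs$inchikey)],
      rank = seq_len(nrow(d)),
      sample_id = d$sample_id,
      food_name = unname(food_by_sample[d$sample_id]),
      genus = unname(gen),
      intensity = d$intensity,
      novel = !is.na(gen) & !(tolower(gen) %in% tolower(known))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(inchikey = character(), compound_name = character(),
                          rank = integer(), sample_id = character(),
                          food_name = character(), genus = character(),
                          intensity = numeric(), novel = logical()))
  }
  out
}
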