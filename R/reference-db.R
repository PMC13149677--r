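# Reference knowledge-base loading and indexing.
#
# Six source kinds are recognized, mirroring the screening design: three
# "drug-like" structure references matched by InChIKey (a pharmaceutical
# reference, a food-contact-chemical reference, an agrochemical reference)
# and three natural-product occurrence references whose molecular formulas
# and producing genera feed the xenobiotic and novel-producer screens.
# Fixtures ship as plain TSV; only (inchikey, name, categories) or
# (inchikey, formula, genus) tuples are ever consumed.

.DRUG_LIKE_SOURCES <- c("drugbank", "fccdb", "agrochem")
.NP_SOURCES <- c("lotus", "coconut", "supernatural")
.ALL_SOURCES <- c(.DRUG_LIKE_SOURCES, .NP_SOURCES)

.INCHIKEY_RE <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

#' Validate InChIKey strings
#'
#' Pattern check only (14 uppercase letters, hyphen, 10 uppercase letters,
#' hyphen, one uppercase letter); no checksum or standard-InChI provenance
#' is verified.
#'
#' @param x Character vector.
#' @return Logical vector.
#' @export
is_valid_inchikey <- function(x) {
  !is.na(x) & grepl(.INCHIKEY_RE, x)
}

.normalize_genus <- function(x) {
  x <- trimws(x)
  out <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  out[is.na(x) | !nzchar(x)] <- NA_character_
  out
}

#' Read one reference table
#'
#' Loads a delimited reference export into a standardized compound table
#' via [as_reference_table()].
#'
#' @param path Path to a TSV (or CSV) file with a header row.
#' @param source_id One of `"drugbank"`, `"fccdb"`, `"agrochem"` (drug-like)
#'   or `"lotus"`, `"coconut"`, `"supernatural"` (natural-product).
#' @param category_delim Delimiter splitting the `categories` field
#'   (default `";"`).
#' @return See [as_reference_table()].
#' @export
read_reference_table <- function(path, source_id,
                                 category_delim = ";") {
  if (!file.exists(path)) {
    stop(sprintf("reference table not found: %s", path), call. = FALSE)
  }
  raw <- .read_delim_auto(path)
  if (nrow(raw) == 0) {
    stop(sprintf("reference table is empty: %s", path), call. = FALSE)
  }
  out <- as_reference_table(raw, source_id, category_delim)
  rep <- attr(out, "load_report")
  rep$path <- path
  attr(out, "load_report") <- rep
  out
}

#' Standardize a raw reference data frame
#'
#' Natural-product sources require columns `inchikey`, `formula`, `genus`;
#' drug-like sources require `inchikey`, `name`, `categories`. Rows with an
#' invalid InChIKey, or (for natural-product sources) an unparseable
#' formula, are dropped and tallied in the load report; duplicate InChIKeys
#' within a source are merged with genera/categories unioned.
#'
#' @param raw Data frame with the source's raw columns.
#' @param source_id One of the six source ids (see
#'   [read_reference_table()]).
#' @param category_delim Delimiter splitting the `categories` field.
#' @return A tibble with columns `inchikey`, `name`, `formula` (canonical
#'   Hill string or `NA`), `source_id`, `categories` (list column),
#'   `genera` (list column of capitalized genus names). The load report
#'   (rows read / kept / dropped per reason) is attached as attribute
#'   `load_report`.
#' @export
as_reference_table <- function(raw, source_id, category_delim = ";") {
  source_id <- match.arg(source_id, .ALL_SOURCES)
  is_np <- source_id %in% .NP_SOURCES
  required <- if (is_np) c("inchikey", "formula", "genus") else
    c("inchikey", "name", "categories")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("reference table (%s) is missing column(s): %s",
                 source_id, paste(missing, collapse = ", ")), call. = FALSE)
  }
  n_read <- nrow(raw)
  ok_key <- is_valid_inchikey(raw$inchikey)
  n_bad_key <- sum(!ok_key)
  raw <- raw[ok_key, , drop = FALSE]

  if (is_np) {
    canon <- canonical_formula(raw$formula)
    n_bad_formula <- sum(is.na(canon))
    raw <- raw[!is.na(canon), , drop = FALSE]
    canon <- canon[!is.na(canon)]
    genera <- .normalize_genus(raw$genus)
    parts <- split(seq_len(nrow(raw)), raw$inchikey)
    out <- dplyr::bind_rows(lapply(parts, function(idx) {
      tibble::tibble(
        inchikey = raw$inchikey[[idx[1]]],
        name = if ("name" %in% names(raw)) raw$name[[idx[1]]] else NA_character_,
        formula = canon[[idx[1]]],
        source_id = source_id,
        categories = list(character(0)),
        genera = list(sort(unique(stats::na.omit(genera[idx]))))
      )
    }))
  } else {
    n_bad_formula <- 0L
    cats <- strsplit(ifelse(is.na(raw$categories), "", raw$categories),
                     category_delim, fixed = TRUE)
    cats <- lapply(cats, function(x) sort(unique(trimws(x[nzchar(trimws(x))]))))
    parts <- split(seq_len(nrow(raw)), raw$inchikey)
    out <- dplyr::bind_rows(lapply(parts, function(idx) {
      tibble::tibble(
        inchikey = raw$inchikey[[idx[1]]],
        name = raw$name[[idx[1]]],
        formula = if ("formula" %in% names(raw))
          canonical_formula(raw$formula[[idx[1]]]) else NA_character_,
        source_id = source_id,
        categories = list(sort(unique(unlist(cats[idx])))),
        genera = list(character(0))
      )
    }))
  }
  out <- out[order(out$inchikey), , drop = FALSE]
  attr(out, "load_report") <- list(
    source_id = source_id, n_read = n_read,
    n_kept = nrow(out), n_dropped_invalid_inchikey = n_bad_key,
    n_dropped_bad_formula = n_bad_formula,
    n_merged_duplicates = (n_read - n_bad_key - n_bad_formula) - nrow(out)
  )
  out
}

#' Build the unified reference index
#'
#' Collapses compound tables from one or more sources into the lookup used
#' by every downstream screen: per-source InChIKey sets, the union of
#' canonical natural-product formulas, a genus-occurrence map keyed by both
#' InChIKey and canonical formula (values unioned over sources), and the
#' therapeutic-category map for pharmaceutical compounds.
#'
#' @param compounds A compound tibble from [read_reference_table()], or a
#'   list of such tibbles (they are row-bound).
#' @return A list of class `reference_index` with fields `inchikey_sets`,
#'   `np_formula_union`, `genus_occurrence`, `category_map`.
#' @export
build_reference_index <- function(compounds) {
  if (is.data.frame(compounds)) compounds <- list(compounds)
  all <- dplyr::bind_rows(compounds)
  stopifnot(all(all$source_id %in% .ALL_SOURCES))

  inchikey_sets <- lapply(stats::setNames(nm = .ALL_SOURCES), function(s) {
    sort(unique(all$inchikey[all$source_id == s]))
  })

  np <- all[all$source_id %in% .NP_SOURCES, , drop = FALSE]
  np_formula_union <- sort(unique(stats::na.omit(np$formula)))

  genus_occurrence <- new.env(parent = emptyenv())
  if (nrow(np) > 0) {
    for (i in seq_len(nrow(np))) {
      gen <- np$genera[[i]]
      if (length(gen) == 0) next
      for (key in unique(c(np$inchikey[[i]], np$formula[[i]]))) {
        if (is.na(key)) next
        prev <- if (exists(key, envir = genus_occurrence)) {
          get(key, envir = genus_occurrence)
        } else character(0)
        assign(key, sort(unique(c(prev, gen))), envir = genus_occurrence)
      }
    }
  }

  drug <- all[all$source_id == "drugbank", , drop = FALSE]
  category_map <- stats::setNames(drug$categories, drug$inchikey)
  category_map <- category_map[lengths(category_map) > 0]

  structure(list(inchikey_sets = inchikey_sets,
                 np_formula_union = np_formula_union,
                 genus_occurrence = genus_occurrence,
                 category_map = category_map),
            class = "reference_index")
}

#' Look up known producing genera for a compound
#'
#' @param index A `reference_index`.
#' @param key InChIKey or canonical Hill formula string.
#' @return Character vector of capitalized genus names (possibly empty).
#' @export
known_genera <- function(index, key) {
  stopifnot(inherits(index, "reference_index"))
  if (is.na(key) || !exists(key, envir = index$genus_occurrence)) {
    return(character(0))
  }
  get(key, envir = index$genus_occurrence)
}

#' Restrict the category map to selected therapeutic categories
#'
#' Therapeutic-category exports mix pharmacological classes with
#' non-therapeutic descriptors (chemical descriptors, industrial uses);
#' analysis keeps a curated set of broad therapeutic categories. Each
#' compound's categories are intersected with `keep`; compounds left with no
#' category drop out of the category map but remain matchable through the
#' InChIKey sets.
#'
#' @param index A `reference_index`.
#' @param keep Non-empty character vector of category names to retain.
#' @return A new `reference_index` with the filtered `category_map`.
#' @export
select_therapeutic_categories <- function(index, keep) {
  stopifnot(inherits(index, "reference_index"), length(keep) > 0)
  filtered <- lapply(index$category_map, function(x) intersect(x, keep))
  index$category_map <- filtered[lengths(filtered) > 0]
  index
}

#' @export
print.reference_index <- function(x, ...) {
  cat("<reference_index>\n")
  for (s in names(x$inchikey_sets)) {
    cat(sprintf("  %-12s %d InChIKeys\n", s, length(x$inchikey_sets[[s]])))
  }
  cat(sprintf("  natural-product formula union: %d formulas\n",
              length(x$np_formula_union)))
  cat(sprintf("  genus occurrence keys: %d\n",
              length(ls(envir = x$genus_occurrence))))
  cat(sprintf("  therapeutic category map: %d compounds\n",
              length(x$category_map)))
  invisible(x)
}
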