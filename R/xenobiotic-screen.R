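# Formula-level xenobiotic screen.
#
# Formula-only features are classified by membership of their canonical Hill
# formula in the union of natural-product reference formulas; absences are
# putative xenobiotics. The non-natural pool is then prioritized by fluorine
# content and profiled by degree of unsaturation and heteroatom composition.
# Structure-annotated features are never screened here, even when their
# formula is absent from the union: the two annotation branches are
# disjoint.

#' Round half away from zero
#'
#' Decimal rounding as printed in reports (0.5 rounds up), as opposed to
#' base R's round-half-to-even. Applied only at report formatting, never
#' inside computations.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Partition summary of the feature table
#'
#' Book-keeping for the two-branch analysis: structure-annotated versus
#' formula-only features, and within the formula-only pool the split between
#' natural-product formula matches and putative xenobiotics. The xenobiotic
#' percentage is reported relative to all features, rounded half-up to one
#' decimal.
#'
#' @param n_structure,n_np_match,n_xenobiotic Stratum counts.
#' @param n_unclassifiable Formula-only features whose formula failed to
#'   parse (kept in an auditable side list, counted in the formula-only
#'   total).
#' @return A list of class `partition_summary` with the counts, the derived
#'   totals and `pct_xenobiotic_of_total`.
#' @export
partition_summary <- function(n_structure, n_np_match, n_xenobiotic,
                              n_unclassifiable = 0) {
  n_formula_only <- n_np_match + n_xenobiotic + n_unclassifiable
  n_total <- n_structure + n_formula_only
  out <- list(
    n_total = n_total,
    n_structure = n_structure,
    n_formula_only = n_formula_only,
    n_np_match = n_np_match,
    n_xenobiotic = n_xenobiotic,
    n_unclassifiable = n_unclassifiable,
    pct_xenobiotic_of_total =
      round_half_up(100 * n_xenobiotic / n_total, 1)
  )
  stopifnot(out$n_structure + out$n_formula_only == out$n_total,
            out$n_np_match + out$n_xenobiotic + out$n_unclassifiable ==
              out$n_formula_only)
  structure(out, class = "partition_summary")
}

#' @export
print.partition_summary <- function(x, ...) {
  cat("<partition_summary>\n")
  cat(sprintf("  total features:        %d\n", x$n_total))
  cat(sprintf("  structure-annotated:   %d\n", x$n_structure))
  cat(sprintf("  formula-only:          %d\n", x$n_formula_only))
  cat(sprintf("    NP formula match:    %d\n", x$n_np_match))
  cat(sprintf("    putative xenobiotic: %d (%.1f%% of all features)\n",
              x$n_xenobiotic, x$pct_xenobiotic_of_total))
  if (x$n_unclassifiable > 0) {
    cat(sprintf("    unclassifiable:      %d\n", x$n_unclassifiable))
  }
  invisible(x)
}

#' Classify formula-only features against the natural-product formula union
#'
#' Each formula-only feature whose canonical Hill formula occurs in the
#' natural-product formula union is called `np_formula_match`; any formula
#' absent from that reference set is called `putative_xenobiotic`. Features
#' whose formula cannot be parsed are routed to an `unclassifiable` side
#' table rather than silently dropped. Per-feature DBE values (NA when the
#' formula contains an element incompatible with the calculation) and
#' heteroatom counts are attached for downstream profiling.
#'
#' @param features Feature tibble (see [match_structures()] for columns).
#' @param index A `reference_index` whose `np_formula_union` defines the
#'   natural-product reference set.
#' @return A list with `calls` (tibble: `feature_id`, `formula`, `call`,
#'   `fluorinated`, `dbe`, `dbe_excluded`, `n_F`, `n_Cl`, `n_Br`, `n_I`,
#'   `n_S`, `n_P`, `halogen_any`), `summary` (a [partition_summary()]) and
#'   `unclassifiable` (tibble: `feature_id`, `formula`, `reason`).
#' @export
classify_features <- function(features, index) {
  features <- .check_feature_table(features)
  stopifnot(inherits(index, "reference_index"))

  fo <- features[features$annotation_level == "formula_only", , drop = FALSE]
  n_structure <- sum(features$annotation_level == "structure")

  parsed <- lapply(fo$formula, function(t) {
    tryCatch(.parse_counts(t), error = function(e) conditionMessage(e))
  })
  ok <- vapply(parsed, is.integer, logical(1))

  unclassifiable <- tibble::tibble(
    feature_id = fo$feature_id[!ok],
    formula = fo$formula[!ok],
    reason = vapply(parsed[!ok], identity, character(1))
  )

  keep <- fo[ok, , drop = FALSE]
  counts_list <- parsed[ok]
  canon <- vapply(counts_list, format_formula, character(1))
  in_np <- canon %in% index$np_formula_union

  het <- t(vapply(counts_list, function(cc) {
    vapply(.HETEROATOMS, .count_of, integer(1), counts = cc)
  }, integer(length(.HETEROATOMS))))
  colnames(het) <- .HETEROATOMS

  dbe <- vapply(counts_list, function(cc) {
    r <- compute_dbe(cc)
    if (r$excluded) NA_real_ else r$value
  }, numeric(1))
  dbe_excluded <- vapply(counts_list, function(cc) {
    length(setdiff(names(cc), .DBE_COMPATIBLE)) > 0
  }, logical(1))

  calls <- tibble::tibble(
    feature_id = keep$feature_id,
    formula = canon,
    call = ifelse(in_np, "np_formula_match", "putative_xenobiotic"),
    fluorinated = het[, "F"] >= 1L & !in_np,
    dbe = dbe,
    dbe_excluded = dbe_excluded,
    n_F = het[, "F"], n_Cl = het[, "Cl"], n_Br = het[, "Br"],
    n_I = het[, "I"], n_S = het[, "S"], n_P = het[, "P"],
    halogen_any = het[, "F"] + het[, "Cl"] + het[, "Br"] + het[, "I"] >= 1L
  )
  calls <- calls[order(calls$feature_id), , drop = FALSE]

  summary <- partition_summary(
    n_structure = n_structure,
    n_np_match = sum(in_np),
    n_xenobiotic = sum(!in_np),
    n_unclassifiable = nrow(unclassifiable)
  )
  list(calls = calls, summary = summary, unclassifiable = unclassifiable)
}

#' Fluorine-prioritized subset of the xenobiotic pool
#'
#' Fluorine is exceptionally rare in biosynthetic products, so
#' fluorine-containing formulas in the non-natural pool are strong
#' candidates for anthropogenic compounds (agrochemicals, pharmaceuticals,
#' PFAS). Retains putative xenobiotics with at least one F atom, ordered by
#' feature id.
#'
#' @param calls The `calls` tibble from [classify_features()].
#' @return Subset tibble with the same columns.
#' @export
filter_fluorinated <- function(calls) {
  out <- calls[calls$call == "putative_xenobiotic" & calls$n_F >= 1L, ,
               drop = FALSE]
  out[order(out$feature_id), , drop = FALSE]
}

#' DBE histogram of the xenobiotic pool
#'
#' Bins the degree-of-unsaturation values of putative xenobiotics (all, and
#' the fluorinated stratum) into left-closed bins of the given width. DBE
#' values are half-integers, so the default width of 1/2 gives one bin per
#' attainable value. Features whose DBE is undefined (incompatible
#' elements) are not binned; their number is recorded in the `n_skipped`
#' attribute.
#'
#' @param calls The `calls` tibble from [classify_features()].
#' @param bin_width Positive bin width (default 0.5).
#' @return A tibble with `bin` (left edge), `n_all`, `n_fluorinated`,
#'   ordered by bin; attribute `n_skipped` counts excluded-DBE xenobiotics.
#' @export
dbe_histogram <- function(calls, bin_width = 0.5) {
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    stop("bin_width must be a positive number", call. = FALSE)
  }
  xeno <- calls[calls$call == "putative_xenobiotic", , drop = FALSE]
  binnable <- !is.na(xeno$dbe)
  bins <- floor(xeno$dbe[binnable] / bin_width) * bin_width
  fl <- xeno$fluorinated[binnable]
  edges <- sort(unique(bins))
  out <- tibble::tibble(
    bin = edges,
    n_all = vapply(edges, function(b) sum(bins == b), integer(1)),
    n_fluorinated = vapply(edges, function(b) sum(bins == b & fl), integer(1))
  )
  attr(out, "n_skipped") <- sum(!binnable)
  out
}

#' Heteroatom summary of the xenobiotic pool
#'
#' Counts, over putative xenobiotics only, the number of features containing
#' at least one atom of each tracked heteroatom (features-containing counts,
#' not atom totals), plus the number of features containing any halogen.
#'
#' @param calls The `calls` tibble from [classify_features()].
#' @return A tibble with columns `element` (F, Cl, Br, I, S, P, and
#'   `any_halogen`) and `n_features`.
#' @export
heteroatom_summary <- function(calls) {
  xeno <- calls[calls$call == "putative_xenobiotic", , drop = FALSE]
  cols <- c(F = "n_F", Cl = "n_Cl", Br = "n_Br", I = "n_I",
            S = "n_S", P = "n_P")
  tibble::tibble(
    element = c(names(cols), "any_halogen"),
    n_features = c(
      vapply(cols, function(col) sum(xeno[[col]] >= 1L), integer(1),
             USE.NAMES = FALSE),
      sum(xeno$halogen_any)
    )
  )
}
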