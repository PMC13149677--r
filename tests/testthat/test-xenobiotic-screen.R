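np_index_of <- function(formulas) {
  build_reference_index(as_reference_table(tibble::tibble(
    inchikey = vapply(seq_along(formulas), function(i) random_inchikey(),
                      character(1)),
    formula = formulas,
    genus = "Malus"
  ), "lotus"))
}

test_that("classification is exact formula-set membership", {
  set.seed(11)
  feats <- tibble::tibble(
    feature_id = c("FT1", "FT2", "FT3", "FT4"),
    annotation_level = c("structure", rep("formula_only", 3)),
    formula = c("C6H6", "C15H10O5", "C8F17KO3S", "O5C15H10"),
    inchikey = c("AAAAAAAAAAAAAA-BBBBBBBBBB-N", NA, NA, NA)
  )
  idx <- np_index_of("C15H10O5")
  res <- classify_features(feats, idx)
  calls <- res$calls
  expect_equal(nrow(calls), 3)  # structure feature excluded from screen
  expect_equal(calls$call[calls$feature_id == "FT2"], "np_formula_match")
  # membership is on canonical Hill strings, so permuted input matches too
  expect_equal(calls$call[calls$feature_id == "FT4"], "np_formula_match")
  expect_equal(calls$call[calls$feature_id == "FT3"], "putative_xenobiotic")
  expect_true(calls$fluorinated[calls$feature_id == "FT3"])
  expect_true(calls$dbe_excluded[calls$feature_id == "FT3"])
  expect_equal(res$summary$n_structure, 1)
  expect_equal(res$summary$n_np_match, 2)
  expect_equal(res$summary$n_xenobiotic, 1)
})

test_that("an empty reference union makes every formula a xenobiotic", {
  feats <- tibble::tibble(
    feature_id = c("FT1", "FT2"),
    annotation_level = "formula_only",
    formula = c("C6H12O6", "C15H10O5"),
    inchikey = NA_character_
  )
  idx <- build_reference_index(as_reference_table(tibble::tibble(
    inchikey = "AAAAAAAAAAAAAA-BBBBBBBBBB-N", name = "x", categories = ""),
    "drugbank"))
  res <- classify_features(feats, idx)
  expect_true(all(res$calls$call == "putative_xenobiotic"))
})

test_that("unparseable formulas are routed to a side list, never dropped", {
  feats <- tibble::tibble(
    feature_id = c("FT1", "FT2"),
    annotation_level = "formula_only",
    formula = c("C6H12O6", "C0H4"),
    inchikey = NA_character_
  )
  res <- classify_features(feats, np_index_of("C6H12O6"))
  expect_equal(res$unclassifiable$feature_id, "FT2")
  expect_match(res$unclassifiable$reason, "zero multiplier")
  expect_equal(res$summary$n_unclassifiable, 1)
  # every formula-only feature lands in exactly one disposition
  expect_equal(res$summary$n_np_match + res$summary$n_xenobiotic +
                 res$summary$n_unclassifiable, 2)
})

test_that("partition conservation holds on the synthetic study", {
  study <- test_study()
  res <- classify_features(study$features, test_index(study))
  s <- res$summary
  expect_equal(s$n_structure + s$n_formula_only, s$n_total)
  expect_equal(s$n_np_match + s$n_xenobiotic + s$n_unclassifiable,
               s$n_formula_only)
  expect_equal(s$pct_xenobiotic_of_total,
               round_half_up(100 * s$n_xenobiotic / s$n_total, 1))
  # planted xenobiotics recovered exactly (brute-force set membership)
  union <- test_index(study)$np_formula_union
  oracle <- study$features$feature_id[
    study$features$annotation_level == "formula_only" &
      !(canonical_formula(study$features$formula) %in% union)]
  called <- res$calls$feature_id[res$calls$call == "putative_xenobiotic"]
  expect_setequal(called, oracle)
  expect_setequal(called, study$ground_truth$xenobiotic_ids)
})

test_that("fluorine filter keeps F-containing xenobiotics only", {
  feats <- tibble::tibble(
    feature_id = c("FT1", "FT2", "FT3"),
    annotation_level = "formula_only",
    formula = c("C8F17KO3S", "C10H14Cl2", "C6F6"),
    inchikey = NA_character_
  )
  res <- classify_features(feats, np_index_of("C20H30O2"))
  fl <- filter_fluorinated(res$calls)
  expect_setequal(fl$feature_id, c("FT1", "FT3"))
  # order-stable by feature id
  expect_equal(fl$feature_id, sort(fl$feature_id))
})

test_that("DBE histogram bins xenobiotics and tallies excluded formulas", {
  feats <- tibble::tibble(
    feature_id = sprintf("FT%d", 1:4),
    annotation_level = "formula_only",
    # DBE 0, 0, 4, and one K-containing exclusion
    formula = c("C2H6", "C3F8", "C6H6O2", "C8F17KO3S"),
    inchikey = NA_character_
  )
  res <- classify_features(feats, np_index_of("C20H30O2"))
  h <- dbe_histogram(res$calls)
  expect_equal(h$n_all[h$bin == 0], 2)
  expect_equal(h$n_all[h$bin == 4], 1)
  expect_equal(sum(h$n_all), 3)
  expect_equal(attr(h, "n_skipped"), 1)
  expect_error(dbe_histogram(res$calls, bin_width = 0), "positive")
})

test_that("fluorinated stratum never exceeds the overall bin count", {
  study <- test_study()
  res <- classify_features(study$features, test_index(study))
  h <- dbe_histogram(res$calls)
  expect_true(all(h$n_fluorinated <= h$n_all))
  n_xeno <- sum(res$calls$call == "putative_xenobiotic")
  expect_equal(sum(h$n_all) + attr(h, "n_skipped"), n_xeno)
})

test_that("heteroatom summary counts features containing each element", {
  feats <- tibble::tibble(
    feature_id = c("FT1", "FT2"),
    annotation_level = "formula_only",
    formula = c("C2HF3", "C3H5FClS"),
    inchikey = NA_character_
  )
  res <- classify_features(feats, np_index_of("C20H30O2"))
  het <- heteroatom_summary(res$calls)
  get <- function(el) het$n_features[het$element == el]
  expect_equal(get("F"), 2)
  expect_equal(get("Cl"), 1)
  expect_equal(get("S"), 1)
  expect_equal(get("P"), 0)
  expect_equal(get("any_halogen"), 2)

  empty <- res$calls[0, ]
  het0 <- heteroatom_summary(empty)
  expect_true(all(het0$n_features == 0))
})
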