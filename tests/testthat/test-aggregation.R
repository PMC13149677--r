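mk_wide <- function() {
  matrix(c(2, 0, 4, 1, 3, 0, 0, 5), nrow = 2, byrow = TRUE,
         dimnames = list(c("FT1", "FT2"), c("A1", "A2", "P1", "P2")))
}

test_that("wide/long conversion preserves every value", {
  wide <- mk_wide()
  long <- to_long(wide)
  expect_equal(nrow(long), 8)
  expect_equal(long$intensity[long$feature_id == "FT1" &
                                long$sample_id == "P1"], 4)
  expect_equal(to_wide(long)[rownames(wide), colnames(wide)], wide)
  bad <- wide
  rownames(bad) <- c("FT1", "FT1")
  expect_error(to_long(bad), "duplicate")
})

test_that("group aggregation computes dense block means and sums", {
  long <- to_long(mk_wide())
  md <- tiny_metadata()
  # animal block of FT1 = {2, 0}; plant block = {4, 1}
  m_mean <- aggregate_by_group(long, md, feature_sets = list(f1 = "FT1"),
                               aggregation = "mean")
  expect_equal(m_mean$values["animal", "f1"], 1)
  expect_equal(m_mean$values["plant", "f1"], 2.5)
  m_sum <- aggregate_by_group(long, md, feature_sets = list(f1 = "FT1"),
                              aggregation = "sum")
  expect_equal(m_sum$values["animal", "f1"], 2)
  # log10(x+1) is applied after aggregation
  long999 <- tibble::tibble(feature_id = "FT1",
                            sample_id = c("A1", "A2"),
                            intensity = c(999, 0))
  m_log <- aggregate_by_group(long999, md[1:2, ],
                              feature_sets = list(f1 = "FT1"),
                              aggregation = "sum", transform = "log10p1")
  expect_equal(m_log$values["animal", "f1"], 3)
  # two-feature blocks include zeros from both features
  m2 <- aggregate_by_group(long, md, feature_sets = list(b = c("FT1", "FT2")),
                           aggregation = "mean")
  expect_equal(m2$values["animal", "b"], (2 + 0 + 3 + 0) / 4)
  expect_warning(
    aggregate_by_group(long, md, feature_sets = list(none = character(0))),
    "empty")
})

test_that("sum aggregation conserves the grand total", {
  study <- test_study()
  long <- to_long(study$abundance)
  ids <- study$ground_truth$drug_ids
  m <- aggregate_by_group(long, study$metadata,
                          feature_sets = list(drug = ids),
                          aggregation = "sum")
  expect_equal(sum(m$values[, "drug"]),
               sum(study$abundance[ids, ]))
  # block means are bounded by block extremes
  mm <- aggregate_by_group(long, study$metadata,
                           feature_sets = list(drug = ids),
                           aggregation = "mean")
  expect_true(all(mm$values[, "drug"] <= max(study$abundance[ids, ])))
  expect_true(all(mm$values[, "drug"] >= min(study$abundance[ids, ])))
})

test_that("the planted plant-sample effect dominates the drug row", {
  study <- test_study()
  long <- to_long(study$abundance)
  m <- aggregate_by_group(long, study$metadata,
                          feature_sets =
                            list(drug = study$ground_truth$drug_ids),
                          aggregation = "mean")
  plant <- m$values["plant", "drug"]
  expect_true(all(plant > m$values[rownames(m$values) != "plant", "drug"]))
})

test_that("top sources ranks foods by mean with deterministic ties", {
  md <- tiny_metadata()
  long <- tibble::tibble(
    feature_id = "FT1",
    sample_id = c("A1", "A2", "P1", "P2"),
    intensity = c(7, 3, 3, 0)
  )
  top <- top_sources(long, md, "FT1", n = 10)
  expect_equal(nrow(top), 3)  # "up to top n": only detected foods
  expect_equal(top$food_name[1], "gouda cheese")
  # tie between "hen egg" and "carrot" broken alphabetically
  expect_equal(top$food_name[2:3], c("carrot", "hen egg"))
  expect_equal(top_sources(long, md, "FT1", n = 2)$food_name,
               c("gouda cheese", "carrot"))
  none <- tibble::tibble(feature_id = "FT1", sample_id = "A1", intensity = 0)
  expect_equal(nrow(top_sources(none, md[1, ], "FT1")), 0)
  expect_error(top_sources(long, md, "NOPE"), "unknown feature")
})

test_that("prevalence reproduces worked detection percentages", {
  md <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:65),
    food_name = sprintf("food %d", 1:65),
    organism_name = "Bos taurus",
    foodon_l1 = "animal"
  )
  long <- tibble::tibble(feature_id = "FT1", sample_id = md$sample_id,
                         intensity = c(rep(1, 63), 0, 0))
  p <- prevalence(long, md, "FT1", population = c(foodon_l1 = "animal"))
  expect_equal(p$k, 63)
  expect_equal(p$n, 65)
  expect_equal(p$percent, 97)
  long$intensity <- 0
  expect_equal(prevalence(long, md, "FT1")$percent, 0)
  long$intensity <- 2
  expect_equal(prevalence(long, md, "FT1")$percent, 100)
  expect_error(prevalence(long, md, "FT1",
                          population = c(foodon_l1 = "plant")), "empty")
})

test_that("detection floor is strict", {
  md <- tiny_metadata()
  long <- tibble::tibble(feature_id = "FT1", sample_id = md$sample_id,
                         intensity = c(5, 5, 5, 4))
  expect_equal(prevalence(long, md, "FT1", detect_min = 5)$k, 0)
  expect_equal(prevalence(long, md, "FT1", detect_min = 4)$k, 3)
})

test_that("fluorinated matrix rows are the union of per-group top-k", {
  study <- test_study()
  idx <- test_index(study)
  res <- classify_features(study$features, idx)
  long <- to_long(study$abundance)
  cm <- top_fluorinated_matrix(res$calls, long, study$metadata,
                               level = "foodon_l1", k = 10)
  expect_false(anyDuplicated(rownames(cm$values)) > 0)
  expect_true(all(rownames(cm$values) %in%
                    study$ground_truth$fluorinated_ids))
  expect_setequal(colnames(cm$values),
                  unique(study$metadata$foodon_l1))
  # identical input yields identical leaf order
  cm2 <- top_fluorinated_matrix(res$calls, long, study$metadata,
                                level = "foodon_l1", k = 10)
  expect_identical(cm$row_order, cm2$row_order)
  expect_identical(cm$col_order, cm2$col_order)
})

test_that("planted dairy cluster keeps hard cheeses together", {
  study <- test_study()
  gt <- study$ground_truth
  idx <- test_index(study)
  res <- classify_features(study$features, idx)
  long <- to_long(study$abundance)
  dairy_samples <- c(gt$hard_cheese_samples, gt$fresh_cheese_samples)
  cm <- top_fluorinated_matrix(res$calls, long, study$metadata,
                               level = "food_name", k = 10,
                               samples = dairy_samples)
  hard_foods <- study$metadata$food_name[
    study$metadata$sample_id %in% gt$hard_cheese_samples]
  pos <- match(hard_foods, cm$col_order)
  # hard-cheese columns are contiguous in the clustered order
  expect_equal(sort(pos), seq(min(pos), max(pos)))
  # the recurring trio is present in hard cheeses, absent in fresh
  expect_true(all(gt$trio_ids %in% rownames(cm$values)))
  fresh_foods <- study$metadata$food_name[
    study$metadata$sample_id %in% gt$fresh_cheese_samples]
  expect_true(all(cm$values[gt$trio_ids, fresh_foods] == 0))
  expect_true(all(cm$values[gt$trio_ids, hard_foods] > 0))
})
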