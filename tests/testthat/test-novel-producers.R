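test_that("genus extraction capitalizes binomials and rejects non-names", {
  expect_equal(extract_genus("Daucus carota"), "Daucus")
  expect_equal(extract_genus("cirsium arvense"), "Cirsium")
  expect_equal(extract_genus("Bos taurus taurus"), "Bos")
  expect_equal(extract_genus("unknown"), NA_character_)
  expect_equal(extract_genus(""), NA_character_)
  expect_equal(extract_genus("Malus"), "Malus")
  expect_equal(extract_genus(c("Vitis vinifera", "sp. 7")),
               c("Vitis", NA))
})

# a four-sample micro-study with one drug-matched compound
mk_micro <- function(known_genus = "Cicer", intensities = c(9, 5, 0, 0)) {
  features <- tibble::tibble(
    feature_id = "FT1",
    annotation_level = "structure",
    formula = "C16H12O5",
    inchikey = "AAAAAAAAAAAAAA-BBBBBBBBBB-N",
    compound_name = "biochanin-like"
  )
  metadata <- tibble::tibble(
    sample_id = c("P1", "P2", "P3", "P4"),
    food_name = c("anise hyssop", "chickpea", "carrot", "apple"),
    organism_name = c("Agastache foeniculum", "Cicer arietinum",
                      "Daucus carota", "Malus domestica"),
    foodon_l1 = "plant",
    foodon_l2 = c("herb", "legume", "vegetable", "fruit")
  )
  abundance <- matrix(intensities, nrow = 1,
                      dimnames = list("FT1", metadata$sample_id))
  drug <- as_reference_table(tibble::tibble(
    inchikey = "AAAAAAAAAAAAAA-BBBBBBBBBB-N", name = "biochanin-like",
    categories = "Phytoestrogens"), "drugbank")
  np <- as_reference_table(tibble::tibble(
    inchikey = "AAAAAAAAAAAAAA-BBBBBBBBBB-N", formula = "C16H12O5",
    genus = known_genus), "lotus")
  list(features = features, abundance = abundance, metadata = metadata,
       index = build_reference_index(list(drug, np)))
}

test_that("a detection outside the known genera yields a novel pair", {
  m <- mk_micro()
  pairs <- screen_novel_producers(m$features, m$abundance, m$metadata,
                                  m$index, prevalence_threshold = 0.6)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$genus, "Agastache")
  expect_equal(pairs$best_sample, "P1")
  expect_equal(pairs$max_intensity, 9)
  # detection in the known producer genus is not a pair
  expect_false("Cicer" %in% pairs$genus)
})

test_that("the prevalence filter strictly excludes ubiquitous compounds", {
  # detected in 2 of 4 plant samples = 0.5
  m <- mk_micro()
  at_half <- screen_novel_producers(m$features, m$abundance, m$metadata,
                                    m$index, prevalence_threshold = 0.5)
  expect_equal(nrow(at_half), 1)  # threshold is strict: 0.5 is not > 0.5
  below <- screen_novel_producers(m$features, m$abundance, m$metadata,
                                  m$index, prevalence_threshold = 0.4)
  expect_equal(nrow(below), 0)
})

test_that("raising the prevalence threshold never removes pairs", {
  study <- test_study()
  idx <- test_index(study)
  thresholds <- c(0.02, 0.05, 0.1, 0.2, 0.5)
  prev <- NULL
  for (th in thresholds) {
    pairs <- screen_novel_producers(study$features, study$abundance,
                                    study$metadata, idx,
                                    prevalence_threshold = th)
    key <- paste(pairs$inchikey, pairs$genus)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("planted pairs are recovered exactly; decoys are excluded", {
  study <- test_study()
  idx <- test_index(study)
  gt <- study$ground_truth
  pairs <- screen_novel_producers(study$features, study$abundance,
                                  study$metadata, idx)
  expect_equal(nrow(pairs), nrow(gt$novel_pairs))
  expect_setequal(paste(pairs$inchikey, pairs$genus),
                  paste(gt$novel_pairs$inchikey, gt$novel_pairs$genus))
  expect_false(any(paste(gt$decoy_pairs$inchikey, gt$decoy_pairs$genus) %in%
                     paste(pairs$inchikey, pairs$genus)))
  # no emitted pair has its genus among the compound's known producers
  for (i in seq_len(nrow(pairs))) {
    expect_false(tolower(pairs$genus[i]) %in%
                   tolower(known_genera(idx, pairs$inchikey[i])))
  }
  # both prevalence denominators behave: the all-samples variant also keeps
  # the planted pairs (planted prevalence is below threshold either way)
  pairs_all <- screen_novel_producers(study$features, study$abundance,
                                      study$metadata, idx,
                                      prevalence_population = "all")
  expect_setequal(paste(pairs_all$inchikey, pairs_all$genus),
                  paste(gt$novel_pairs$inchikey, gt$novel_pairs$genus))
})

test_that("screen output matches a brute-force pair enumeration", {
  study <- test_study()
  idx <- test_index(study)
  flags <- match_structures(study$features, idx)
  drug_feats <- study$features[study$features$feature_id %in%
                                 flags$feature_id[flags$matched_drug], ]
  plant_ids <- study$metadata$sample_id[study$metadata$foodon_l1 == "plant"]
  genus_of <- setNames(extract_genus(study$metadata$organism_name),
                       study$metadata$sample_id)
  expected <- list()
  for (i in seq_len(nrow(drug_feats))) {
    row <- study$abundance[drug_feats$feature_id[i], ]
    det <- names(row)[row > 0]
    if (sum(det %in% plant_ids) / length(plant_ids) > 0.10) next
    known <- tolower(known_genera(idx, drug_feats$inchikey[i]))
    for (s in det) {
      g <- genus_of[[s]]
      if (!is.na(g) && !(tolower(g) %in% known)) {
        expected[[paste(drug_feats$inchikey[i], g)]] <- TRUE
      }
    }
  }
  pairs <- screen_novel_producers(study$features, study$abundance,
                                  study$metadata, idx)
  expect_setequal(paste(pairs$inchikey, pairs$genus), names(expected))
})

test_that("producer rankings order by intensity with novel flags", {
  m <- mk_micro(intensities = c(9, 5, 5, 0))
  pairs <- screen_novel_producers(m$features, m$abundance, m$metadata,
                                  m$index, prevalence_threshold = 0.9)
  ranking <- rank_producers(pairs, m$features, m$abundance, m$metadata,
                            m$index)
  expect_equal(ranking$rank, 1:3)
  expect_equal(ranking$sample_id[1], "P1")  # novel producer on top
  expect_true(ranking$novel[1])
  expect_false(ranking$novel[ranking$sample_id == "P2"])  # known genus
  # intensity tie between P2 and P3 broken by sample id
  expect_equal(ranking$sample_id[2:3], c("P2", "P3"))
})

test_that("misaligned abundance and metadata sample ids error", {
  m <- mk_micro()
  colnames(m$abundance)[1] <- "ZZZ"
  expect_error(
    screen_novel_producers(m$features, m$abundance, m$metadata, m$index),
    "ZZZ")
})
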