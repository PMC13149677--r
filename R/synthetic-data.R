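# Seed-reproducible synthetic study generator.
#
# Emulates a food-metabolomics release at desk scale: a features x samples
# normalized intensity matrix, per-feature annotations (a small
# structure-annotated stratum with InChIKeys, a large formula-only
# stratum), FoodOn-style sample metadata with organism binomials, and
# reference fixtures for all six knowledge-base sources -- with planted,
# machine-readable ground truth for every downstream screen: xenobiotic
# formulas constructed to be absent from the natural-product union,
# fluorinated candidates, drug/food-contact/agrochemical InChIKey matches,
# novel compound-genus pairs below the prevalence threshold (plus decoys
# above it), a dairy cluster of recurring fluorinated features, and a
# group-level intensity effect.

.PLANT_GENERA <- c(
  "Daucus", "Malus", "Glycine", "Cirsium", "Agastache", "Portulaca",
  "Malva", "Prunus", "Passiflora", "Mentha", "Thymus", "Ocimum", "Citrus",
  "Vitis", "Triticum", "Zea", "Oryza", "Solanum", "Brassica", "Allium",
  "Capsicum", "Cucumis", "Fragaria", "Rubus", "Vaccinium", "Persea",
  "Olea", "Coffea", "Camellia", "Theobroma", "Cicer", "Lens", "Phaseolus",
  "Arachis", "Helianthus", "Sesamum", "Avena", "Hordeum", "Secale",
  "Spinacia"
)
.ANIMAL_GENERA <- c("Bos", "Gallus", "Sus", "Ovis", "Capra", "Salmo",
                    "Oncorhynchus", "Gadus", "Acheta", "Apis")
.ALGAL_GENERA <- c("Saccharina", "Porphyra", "Ulva", "Chlorella")
.FUNGAL_GENERA <- c("Agaricus", "Lentinula", "Pleurotus", "Flammulina")

.EPITHETS <- c("sativa", "vulgaris", "officinalis", "esculentum", "communis",
               "annuus", "maxima", "arvensis", "domestica", "tinctoria",
               "carota", "edulis", "persica", "sylvestris", "oleracea")

.SUPERCLASSES <- c("Lipids and lipid-like molecules",
                   "Phenylpropanoids and polyketides",
                   "Organic acids and derivatives",
                   "Organoheterocyclic compounds",
                   "Benzenoids")

.THERAPEUTIC_CATS <- c(
  "Enzyme Inhibitors", "Antioxidants", "Anticoagulants",
  "Anti-Inflammatory Agents", "Analgesics", "Antineoplastic Agents",
  "Phytoestrogens", "Antihypertensive Agents", "Antimicrobial Agents",
  "Antifungal Agents", "Antiviral Agents", "Antidiabetic Agents",
  "Neuroprotective Agents", "Anticarcinogenic Agents",
  "Immunomodulating Agents", "Antiparasitic Agents",
  "Bronchodilator Agents", "Diuretics", "Hypolipidemic Agents",
  "Vasodilator Agents"
)
.NON_THERAPEUTIC_CATS <- c("Industrial Dyes", "Chemical Descriptors",
                           "Laboratory Reagents", "Food Additive Carriers")

# Recurring fluorinated features planted in hard-cheese samples, and the
# perfluorooctanesulfonate potassium salt planted across the dairy cluster.
.DAIRY_TRIO_FORMULAS <- c("C33H35FN2O5", "C21H23ClFNO2", "C23H27FN4O2")
.PFOS_K_FORMULA <- "C8F17KO3S"

#' Synthetic study configuration
#'
#' Defaults describe the desk-scale study used throughout the test suite:
#' 2,000 features (100 structure-annotated, 1,900 formula-only) over 100
#' samples split 70/15/8/7 across plant, animal, algal and fungus products
#' -- the same 70%-plant, 15%-animal composition as the full-scale release
#' this generator emulates, at 1/5 of its sample count. Planted counts
#' (xenobiotics at ~4.8% of features, 12/5/2 drug-like matches, 7 novel
#' pairs with 3 over-prevalence decoys) keep every downstream tally small
#' enough to verify by hand.
#'
#' @param seed Integer seed; fixed seed implies identical output.
#' @param n_samples Named integer vector of samples per FoodOn level-1
#'   group (`plant`, `animal`, `algal`, `fungus`).
#' @param n_structure Number of structure-annotated features.
#' @param n_formula_only Number of formula-only features.
#' @param n_np_reference Natural-product reference compounds across the
#'   three occurrence databases.
#' @param n_xenobiotic Formula-only features planted with formulas absent
#'   from the natural-product union.
#' @param n_fluorinated Of the planted xenobiotics, how many contain
#'   fluorine (must include room for the 4 fixed dairy-cluster formulas).
#' @param n_drug,n_fcc,n_agrochem Structure features planted as InChIKey
#'   matches in each drug-like source (disjoint sets).
#' @param n_novel_pairs Planted novel compound-genus pairs (prevalence kept
#'   below the threshold).
#' @param n_decoy_pairs Planted decoy compounds whose detection prevalence
#'   exceeds the threshold (must be screened out).
#' @param zero_fraction Fraction of zero cells in the base intensity
#'   matrix.
#' @param meanlog,sdlog Log-normal intensity parameters for non-zero cells.
#' @param group_effect Multiplier applied to drug-matched features in plant
#'   samples (planted group-level signal).
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1,
                         n_samples = c(plant = 70, animal = 15,
                                       algal = 8, fungus = 7),
                         n_structure = 100,
                         n_formula_only = 1900,
                         n_np_reference = 500,
                         n_xenobiotic = 96,
                         n_fluorinated = 30,
                         n_drug = 12,
                         n_fcc = 5,
                         n_agrochem = 2,
                         n_novel_pairs = 7,
                         n_decoy_pairs = 3,
                         zero_fraction = 0.6,
                         meanlog = 7,
                         sdlog = 1.5,
                         group_effect = 10) {
  cfg <- list(seed = as.integer(seed), n_samples = n_samples,
              n_structure = n_structure, n_formula_only = n_formula_only,
              n_np_reference = n_np_reference, n_xenobiotic = n_xenobiotic,
              n_fluorinated = n_fluorinated, n_drug = n_drug, n_fcc = n_fcc,
              n_agrochem = n_agrochem, n_novel_pairs = n_novel_pairs,
              n_decoy_pairs = n_decoy_pairs, zero_fraction = zero_fraction,
              meanlog = meanlog, sdlog = sdlog, group_effect = group_effect)
  stopifnot(all(c("plant", "animal", "algal", "fungus") %in%
                  names(n_samples)),
            n_xenobiotic <= n_formula_only,
            n_fluorinated >= 4, n_fluorinated <= n_xenobiotic,
            n_drug + n_fcc + n_agrochem <= n_structure,
            n_novel_pairs + n_decoy_pairs <= n_drug,
            zero_fraction >= 0, zero_fraction < 1,
            n_samples[["plant"]] >= 10)
  structure(cfg, class = "study_config")
}

.random_inchikeys <- function(n) {
  keys <- character(0)
  while (length(keys) < n) {
    more <- vapply(seq_len(n - length(keys)), function(i) {
      paste0(paste(sample(LETTERS, 14, replace = TRUE), collapse = ""), "-",
             paste(sample(LETTERS, 10, replace = TRUE), collapse = ""), "-N")
    }, character(1))
    keys <- unique(c(keys, more))
  }
  keys
}

# CHNO(S,P) grammar for biogenic-looking formulas.
.random_np_formula <- function() {
  cc <- sample(5:40, 1)
  h <- sample(seq(max(2, cc %/% 2), 2 * cc + 2), 1)
  counts <- c(C = cc, H = h)
  o <- sample(0:12, 1)
  if (o > 0) counts["O"] <- o
  n <- sample(0:4, 1, prob = c(0.5, 0.25, 0.15, 0.07, 0.03))
  if (n > 0) counts["N"] <- n
  if (stats::runif(1) < 0.10) counts["S"] <- sample(1:2, 1)
  if (stats::runif(1) < 0.05) counts["P"] <- 1
  format_formula(counts)
}

.random_fluorinated_formula <- function() {
  cc <- sample(4:20, 1)
  f <- sample(1:min(17, 2 * cc + 1), 1)
  # bias toward full saturation (DBE 0), the signature of perfluoroalkyl
  # chemistry
  h <- if (stats::runif(1) < 0.6) max(0, 2 * cc + 2 - f) else
    sample(0:max(0, 2 * cc + 1 - f), 1)
  counts <- c(C = cc)
  if (h > 0) counts["H"] <- h
  counts["F"] <- f
  o <- sample(0:4, 1)
  if (o > 0) counts["O"] <- o
  if (stats::runif(1) < 0.2) counts["S"] <- 1
  format_formula(counts)
}

.random_halogenated_formula <- function(halogen) {
  cc <- sample(5:25, 1)
  x <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
  h <- sample(seq(max(1, cc %/% 2), 2 * cc + 1 - x), 1)
  counts <- c(C = cc, H = h)
  counts[halogen] <- x
  o <- sample(0:6, 1)
  if (o > 0) counts["O"] <- o
  if (stats::runif(1) < 0.3) counts["N"] <- sample(1:2, 1)
  format_formula(counts)
}

#' Generate a complete synthetic study with planted ground truth
#'
#' See [study_config()] for what is planted. The generator is deterministic
#' in the config seed, and random-number use is re-seeded per table
#' (metadata, references, features, intensities) so a change in one table's
#' size does not perturb the others.
#'
#' Xenobiotic formula absence from the natural-product union is enforced
#' constructively: halogenated and metal-containing plants cannot occur in
#' the CHNO(S,P) natural-product grammar, and plain-CHNO plants are
#' rejection-sampled against the realized union.
#'
#' @param config A [study_config()].
#' @return A list of class `synthetic_study`: `features` (annotation
#'   tibble), `abundance` (features x samples matrix), `metadata` (sample
#'   tibble), `references` (named list of raw reference tibbles, one per
#'   source), `ground_truth` (planted ids and pairs), `config`.
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  n_total_samples <- sum(config$n_samples)
  n_features <- config$n_structure + config$n_formula_only

  ## ---- metadata -------------------------------------------------------
  set.seed(config$seed)
  groups <- rep(names(config$n_samples), times = config$n_samples)
  pools <- list(plant = .PLANT_GENERA, animal = .ANIMAL_GENERA,
                algal = .ALGAL_GENERA, fungus = .FUNGAL_GENERA)
  l2_pools <- list(plant = c("fruit", "vegetable", "grain", "herb",
                             "legume", "nut"),
                   animal = c("meat", "fish", "egg", "insect"),
                   algal = c("seaweed", "microalga"),
                   fungus = c("mushroom"))
  genus <- vapply(groups, function(g) sample(pools[[g]], 1), character(1))
  epithet <- sample(.EPITHETS, n_total_samples, replace = TRUE)
  foodon_l2 <- vapply(groups, function(g) sample(l2_pools[[g]], 1),
                      character(1))
  metadata <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n_total_samples)),
    food_name = make.unique(paste(tolower(genus), epithet), sep = " "),
    organism_name = paste(genus, epithet),
    foodon_l1 = groups,
    foodon_l2 = foodon_l2
  )

  # dairy cluster: first 7 animal samples become dairy products (4 hard
  # cheeses, 3 fresh cheeses) when the animal stratum is large enough
  animal_idx <- which(metadata$foodon_l1 == "animal")
  dairy <- list(hard = character(0), fresh = character(0))
  if (length(animal_idx) >= 7) {
    hard_idx <- animal_idx[1:4]
    fresh_idx <- animal_idx[5:7]
    metadata$food_name[hard_idx] <- c("gouda cheese", "parmesan cheese",
                                      "cheddar cheese", "manchego cheese")
    metadata$food_name[fresh_idx] <- c("fresh mozzarella", "cottage cheese",
                                       "ricotta cheese")
    metadata$organism_name[c(hard_idx, fresh_idx)] <- "Bos taurus"
    metadata$foodon_l2[c(hard_idx, fresh_idx)] <- "dairy"
    dairy$hard <- metadata$sample_id[hard_idx]
    dairy$fresh <- metadata$sample_id[fresh_idx]
  }

  ## ---- natural-product references -------------------------------------
  set.seed(config$seed + 1000003L)
  np_formulas <- unique(vapply(seq_len(config$n_np_reference),
                               function(i) .random_np_formula(),
                               character(1)))
  np_keys <- .random_inchikeys(length(np_formulas))
  all_genera <- unlist(pools, use.names = FALSE)
  np_rows <- lapply(seq_along(np_formulas), function(i) {
    gen <- sample(all_genera, sample(1:3, 1))
    src <- sample(.NP_SOURCES, sample(1:2, 1))
    expand.grid(inchikey = np_keys[[i]], formula = np_formulas[[i]],
                genus = gen, source = src, stringsAsFactors = FALSE)
  })
  np_rows <- dplyr::bind_rows(np_rows)
  np_union <- sort(unique(np_formulas))

  ## ---- features -------------------------------------------------------
  set.seed(config$seed + 2000003L)
  feature_ids <- sprintf("FT%05d", seq_len(n_features))
  struct_ids <- feature_ids[seq_len(config$n_structure)]
  fo_ids <- feature_ids[-seq_len(config$n_structure)]

  struct_keys <- .random_inchikeys(config$n_structure)
  struct_formulas <- vapply(seq_len(config$n_structure),
                            function(i) .random_np_formula(), character(1))

  drug_ids <- struct_ids[seq_len(config$n_drug)]
  fcc_ids <- struct_ids[config$n_drug + seq_len(config$n_fcc)]
  agro_ids <- struct_ids[config$n_drug + config$n_fcc +
                           seq_len(config$n_agrochem)]

  # xenobiotic formulas: the four fixed dairy-cluster formulas first, then
  # random fluorinated ones, then non-fluorinated halogenated / metal /
  # plain-CHNO plants
  n_fl_random <- config$n_fluorinated - 4L
  fl_formulas <- c(.DAIRY_TRIO_FORMULAS, .PFOS_K_FORMULA,
                   vapply(seq_len(n_fl_random),
                          function(i) .random_fluorinated_formula(),
                          character(1)))
  n_nonf <- config$n_xenobiotic - config$n_fluorinated
  n_cl <- min(n_nonf, max(0L, round(0.35 * n_nonf)))
  n_br <- min(n_nonf - n_cl, max(0L, round(0.08 * n_nonf)))
  n_i <- min(n_nonf - n_cl - n_br, max(0L, round(0.05 * n_nonf)))
  n_metal <- min(n_nonf - n_cl - n_br - n_i, 1L)
  n_plain <- n_nonf - n_cl - n_br - n_i - n_metal
  nonf_formulas <- c(
    vapply(seq_len(n_cl), function(i) .random_halogenated_formula("Cl"),
           character(1)),
    vapply(seq_len(n_br), function(i) .random_halogenated_formula("Br"),
           character(1)),
    vapply(seq_len(n_i), function(i) .random_halogenated_formula("I"),
           character(1)),
    if (n_metal >= 1) "C10H15NaO5S",
    vapply(seq_len(n_plain), function(i) {
      repeat {
        f <- .random_np_formula()
        if (!(f %in% np_union)) return(f)
      }
    }, character(1))
  )
  xeno_formulas <- c(fl_formulas, nonf_formulas)
  xeno_ids <- fo_ids[seq_len(config$n_xenobiotic)]
  fluorinated_ids <- fo_ids[seq_len(config$n_fluorinated)]
  trio_ids <- fo_ids[1:3]
  pfos_id <- fo_ids[4]

  natural_formulas <- sample(np_union, config$n_formula_only -
                               config$n_xenobiotic, replace = TRUE)

  features <- tibble::tibble(
    feature_id = feature_ids,
    annotation_level = c(rep("structure", config$n_structure),
                         rep("formula_only", config$n_formula_only)),
    formula = c(struct_formulas, xeno_formulas, natural_formulas),
    inchikey = c(struct_keys, rep(NA_character_, config$n_formula_only)),
    compound_name = c(sprintf("compound_%03d", seq_len(config$n_structure)),
                      rep(NA_character_, config$n_formula_only)),
    superclass = c(sample(.SUPERCLASSES, config$n_structure, replace = TRUE),
                   rep(NA_character_, config$n_formula_only))
  )

  ## ---- drug-like references -------------------------------------------
  set.seed(config$seed + 3000003L)
  make_drug_like <- function(planted_ids, n_decoys, with_cats) {
    planted_keys <- features$inchikey[match(planted_ids,
                                            features$feature_id)]
    keys <- c(planted_keys, .random_inchikeys(n_decoys))
    names <- c(features$compound_name[match(planted_ids,
                                            features$feature_id)],
               sprintf("reference_%03d", seq_len(n_decoys)))
    cats <- if (with_cats) {
      vapply(seq_along(keys), function(i) {
        k <- sample(1:3, 1)
        base <- sample(.THERAPEUTIC_CATS, k)
        if (stats::runif(1) < 0.3) {
          base <- c(base, sample(.NON_THERAPEUTIC_CATS, 1))
        }
        paste(base, collapse = ";")
      }, character(1))
    } else {
      rep("", length(keys))
    }
    tibble::tibble(inchikey = keys, name = names, categories = cats)
  }
  drugbank <- make_drug_like(drug_ids, 20, with_cats = TRUE)
  # two decoys carrying only non-therapeutic terms, to exercise category
  # selection
  only_bad <- .random_inchikeys(2)
  drugbank <- dplyr::bind_rows(drugbank, tibble::tibble(
    inchikey = only_bad,
    name = sprintf("reference_nt_%d", 1:2),
    categories = vapply(1:2, function(i) {
      paste(sample(.NON_THERAPEUTIC_CATS, 2), collapse = ";")
    }, character(1))
  ))
  fccdb <- make_drug_like(fcc_ids, 15, with_cats = FALSE)
  agrochem <- make_drug_like(agro_ids, 10, with_cats = FALSE)

  ## ---- novel-producer planting ----------------------------------------
  set.seed(config$seed + 4000003L)
  plant_samples <- metadata[metadata$foodon_l1 == "plant", , drop = FALSE]
  plant_genus <- extract_genus(plant_samples$organism_name)
  n_plant <- nrow(plant_samples)

  novel_feat <- drug_ids[seq_len(config$n_novel_pairs)]
  decoy_feat <- drug_ids[config$n_novel_pairs +
                           seq_len(config$n_decoy_pairs)]
  broad_feat <- setdiff(drug_ids, c(novel_feat, decoy_feat))

  novel_pairs <- list()
  extra_np_rows <- list()
  planted_cells <- list()  # (feature_id, sample_id, intensity)

  pick_distinct <- function(exclude_genus, k) {
    ok <- which(plant_genus != exclude_genus)
    sample(ok, k)
  }
  for (i in seq_along(novel_feat)) {
    fid <- novel_feat[[i]]
    key <- features$inchikey[match(fid, features$feature_id)]
    s_idx <- sample(n_plant, 1)
    g_novel <- plant_genus[[s_idx]]
    tu <- pick_distinct(g_novel, 2)
    known <- unique(plant_genus[tu])
    extra_np_rows[[length(extra_np_rows) + 1]] <- tibble::tibble(
      inchikey = key,
      formula = features$formula[match(fid, features$feature_id)],
      genus = known, source = "lotus"
    )
    planted_cells[[length(planted_cells) + 1]] <- tibble::tibble(
      feature_id = fid,
      sample_id = plant_samples$sample_id[c(s_idx, tu)],
      intensity = c(5e5, 1e4, 5e3)
    )
    novel_pairs[[i]] <- tibble::tibble(inchikey = key, genus = g_novel)
  }
  novel_pairs <- dplyr::bind_rows(novel_pairs)

  decoy_pairs <- list()
  n_decoy_det <- max(ceiling(0.15 * n_plant), 2L)
  for (i in seq_along(decoy_feat)) {
    fid <- decoy_feat[[i]]
    key <- features$inchikey[match(fid, features$feature_id)]
    det_idx <- sample(n_plant, n_decoy_det)
    g_novel <- plant_genus[[det_idx[[1]]]]
    known <- setdiff(unique(plant_genus[det_idx[-1]]), g_novel)
    if (length(known) > 0) {
      extra_np_rows[[length(extra_np_rows) + 1]] <- tibble::tibble(
        inchikey = key,
        formula = features$formula[match(fid, features$feature_id)],
        genus = known, source = "lotus"
      )
    }
    planted_cells[[length(planted_cells) + 1]] <- tibble::tibble(
      feature_id = fid,
      sample_id = plant_samples$sample_id[det_idx],
      intensity = stats::rlnorm(n_decoy_det, config$meanlog, config$sdlog)
    )
    decoy_pairs[[i]] <- tibble::tibble(inchikey = key, genus = g_novel)
  }
  decoy_pairs <- dplyr::bind_rows(decoy_pairs)

  # remaining drug-matched compounds: broadly detected (well above the
  # prevalence threshold, so the novel screen must drop them)
  for (fid in broad_feat) {
    det <- metadata$sample_id[seq(1, n_total_samples, by = 2)]
    planted_cells[[length(planted_cells) + 1]] <- tibble::tibble(
      feature_id = fid, sample_id = det,
      intensity = stats::rlnorm(length(det), config$meanlog, config$sdlog)
    )
  }

  np_rows <- dplyr::bind_rows(np_rows, dplyr::bind_rows(extra_np_rows))

  ## ---- intensities ----------------------------------------------------
  set.seed(config$seed + 5000003L)
  abundance <- matrix(
    stats::rlnorm(n_features * n_total_samples, config$meanlog,
                  config$sdlog),
    nrow = n_features,
    dimnames = list(feature_ids, metadata$sample_id)
  )
  zeros <- matrix(stats::runif(n_features * n_total_samples) <
                    config$zero_fraction,
                  nrow = n_features)
  abundance[zeros] <- 0

  # drug-matched rows are fully controlled by the planted detections
  abundance[drug_ids, ] <- 0
  cells <- dplyr::bind_rows(planted_cells)
  abundance[cbind(match(cells$feature_id, feature_ids),
                  match(cells$sample_id, metadata$sample_id))] <-
    cells$intensity

  # dairy cluster: the recurring fluorinated trio is confined to hard
  # cheeses; the perfluorinated salt spans all dairy, stronger in aged
  # cheese
  if (length(dairy$hard) > 0) {
    abundance[trio_ids, ] <- 0
    abundance[trio_ids, dairy$hard] <-
      stats::rlnorm(length(trio_ids) * length(dairy$hard), log(1e6), 0.2)
    abundance[pfos_id, ] <- 0
    abundance[pfos_id, dairy$fresh] <-
      stats::rlnorm(length(dairy$fresh), log(2e3), 0.3)
    abundance[pfos_id, dairy$hard] <-
      stats::rlnorm(length(dairy$hard), log(1e5), 0.3)
  }

  # planted group effect: drug-matched intensities amplified in plant
  # samples
  plant_cols <- metadata$sample_id[metadata$foodon_l1 == "plant"]
  abundance[drug_ids, plant_cols] <-
    abundance[drug_ids, plant_cols] * config$group_effect

  ## ---- assemble references --------------------------------------------
  references <- lapply(stats::setNames(nm = .NP_SOURCES), function(s) {
    sub <- np_rows[np_rows$source == s, c("inchikey", "formula", "genus")]
    tibble::as_tibble(sub[order(sub$inchikey, sub$genus), , drop = FALSE])
  })
  references$drugbank <- drugbank
  references$fccdb <- fccdb
  references$agrochem <- agrochem

  ground_truth <- list(
    xenobiotic_ids = xeno_ids,
    fluorinated_ids = fluorinated_ids,
    dbe_excluded_ids = fo_ids[which(
      vapply(xeno_formulas, function(f) {
        compute_dbe(f)$excluded
      }, logical(1)))],
    drug_ids = drug_ids, fcc_ids = fcc_ids, agrochem_ids = agro_ids,
    novel_pairs = novel_pairs, decoy_pairs = decoy_pairs,
    trio_ids = trio_ids, pfos_id = pfos_id,
    hard_cheese_samples = dairy$hard, fresh_cheese_samples = dairy$fresh,
    zero_fraction = config$zero_fraction
  )

  structure(list(features = features, abundance = abundance,
                 metadata = metadata, references = references,
                 ground_truth = ground_truth, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>\n")
  cat(sprintf("  %d features (%d structure, %d formula-only) x %d samples\n",
              nrow(x$features), x$config$n_structure,
              x$config$n_formula_only, ncol(x$abundance)))
  cat(sprintf("  planted: %d xenobiotics (%d fluorinated), %d novel pairs\n",
              x$config$n_xenobiotic, x$config$n_fluorinated,
              x$config$n_novel_pairs))
  invisible(x)
}
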