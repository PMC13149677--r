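# Shared fixtures, built in code.

# One default synthetic study reused across test files (generation is
# deterministic, so sharing is safe).
.study_cache <- new.env(parent = emptyenv())
test_study <- function(seed = 42) {
  key <- as.character(seed)
  if (!exists(key, envir = .study_cache)) {
    assign(key, generate_study(study_config(seed = seed)),
           envir = .study_cache)
  }
  get(key, envir = .study_cache)
}

test_index <- function(study = test_study()) {
  build_reference_index(lapply(names(study$references), function(s) {
    as_reference_table(study$references[[s]], s)
  }))
}

random_inchikey <- function() {
  paste0(paste(sample(LETTERS, 14, replace = TRUE), collapse = ""), "-",
         paste(sample(LETTERS, 10, replace = TRUE), collapse = ""), "-N")
}

# Random element-count vector over the DBE-compatible set, built directly
# (never through the package's parser) so it can drive independent oracles.
random_compatible_counts <- function() {
  counts <- c(C = sample(1:40, 1), H = sample(0:80, 1))
  counts <- counts[counts > 0]
  for (el in c("N", "O", "S", "P", "F", "Cl", "Br", "I")) {
    if (runif(1) < 0.3) counts[el] <- sample(1:6, 1)
  }
  counts
}

# Independent brute-force evaluation of the unsaturation equation
# DBE = C - (H + F + Cl + Br + I)/2 + N/2 + 1 straight from a count vector.
oracle_dbe <- function(counts) {
  g <- function(el) if (el %in% names(counts)) counts[[el]] else 0
  g("C") - (g("H") + g("F") + g("Cl") + g("Br") + g("I")) / 2 +
    g("N") / 2 + 1
}

# Hill-order oracle: C, H, then alphabetical; alphabetical throughout when
# carbon is absent.
oracle_hill <- function(counts) {
  syms <- names(counts)
  ord <- if ("C" %in% syms) {
    c("C", intersect("H", syms), sort(setdiff(syms, c("C", "H"))))
  } else {
    sort(syms)
  }
  paste0(vapply(ord, function(s) {
    if (counts[[s]] == 1) s else paste0(s, counts[[s]])
  }, character(1)), collapse = "")
}

# Minimal four-sample metadata + matching long table for aggregation tests.
tiny_metadata <- function() {
  tibble::tibble(
    sample_id = c("A1", "A2", "P1", "P2"),
    food_name = c("gouda cheese", "hen egg", "carrot", "apple"),
    organism_name = c("Bos taurus", "Gallus gallus",
                      "Daucus carota", "Malus domestica"),
    foodon_l1 = c("animal", "animal", "plant", "plant"),
    foodon_l2 = c("dairy", "egg", "vegetable", "fruit")
  )
}

write_reference_fixture <- function(df, dir = withr::local_tempdir(),
                                    name = "lotus") {
  path <- file.path(dir, paste0(name, ".tsv"))
  readr::write_tsv(df, path)
  path
}
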