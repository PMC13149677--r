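# Molecular formula parsing and elemental descriptors.
#
# Formulas are flat neutral elemental compositions ("C8F17KO3S"); no charges,
# isotopes, adducts, hydrates or parentheses. The canonical rendering is Hill
# order: C first, then H, then all remaining elements alphabetically; with no
# carbon, every element (H included) sorts alphabetically.

# All 118 IUPAC element symbols; greedy tokenization tries the two-letter
# symbol before the one-letter one, so "Cl" is never read as C + l.
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

# Elements with a defined contribution (possibly zero) to the degree of
# unsaturation: DBE = C - (H + halogens)/2 + N/2 + 1. Formulas containing
# any other element (K, Na, metals, ...) are excluded from the calculation.
.DBE_COMPATIBLE <- c("C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I")

.HETEROATOMS <- c("S", "P", "F", "Cl", "Br", "I")
.HALOGENS <- c("F", "Cl", "Br", "I")

# Map Unicode subscript digits to ASCII; underscores used as subscript
# markers ("C_8F_17KO_3S") are stripped outright.
.normalize_formula_text <- function(text) {
  text <- gsub("[[:space:]_]+", "", text)
  chartr("₀₁₂₃₄₅₆₇₈₉",
         "0123456789", text)
}

.parse_counts <- function(text) {
  raw <- text
  text <- .normalize_formula_text(text)
  if (!nzchar(text)) {
    stop("empty formula string", call. = FALSE)
  }
  unsupported <- "[][(){}.+-]"
  if (grepl(unsupported, text)) {
    bad <- regmatches(text, regexpr(unsupported, text))
    stop(sprintf("unsupported token '%s' in formula '%s' (parentheses, charges, isotopes and hydrates are not accepted)",
                 bad, raw), call. = FALSE)
  }
  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regmatches(rest, regexpr("^([A-Z][a-z]?)([0-9]*)", rest))
    if (length(m) == 0 || !nzchar(m)) {
      stop(sprintf("malformed token at '%s' in formula '%s'", rest, raw),
           call. = FALSE)
    }
    sym <- regmatches(rest, regexpr("^[A-Z][a-z]?", rest))
    # greedy two-letter symbol, fall back to one letter ("Cf" in "CF4"? no:
    # uppercase F never forms a two-letter symbol with C, but e.g. "Co" vs
    # "C" + "O" is disambiguated by case alone)
    if (!(sym %in% .ELEMENTS)) {
      sym1 <- substr(sym, 1, 1)
      if (nchar(sym) == 2L && sym1 %in% .ELEMENTS) {
        sym <- sym1
      } else {
        stop(sprintf("unknown element symbol '%s' in formula '%s'", sym, raw),
             call. = FALSE)
      }
    }
    pos <- pos + nchar(sym)
    rest <- substr(text, pos, n)
    digits <- regmatches(rest, regexpr("^[0-9]+", rest))
    if (length(digits) == 1L && nzchar(digits)) {
      k <- suppressWarnings(as.integer(digits))
      if (is.na(k)) {
        stop(sprintf("count '%s' out of range in formula '%s'", digits, raw),
             call. = FALSE)
      }
      if (k == 0L) {
        stop(sprintf("zero multiplier for element '%s' in formula '%s'",
                     sym, raw), call. = FALSE)
      }
      pos <- pos + nchar(digits)
    } else {
      k <- 1L
    }
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + k else k
  }
  counts
}

#' Parse a molecular formula string
#'
#' Parses a flat neutral molecular formula such as `"C21H23ClFNO2"` into an
#' element-count map. Underscores and Unicode subscript digits used as
#' typographic subscript markers are accepted (`"C_8F_17KO_3S"` parses the
#' same as `"C8F17KO3S"`); repeated element tokens accumulate. Parentheses,
#' charges, isotope labels and hydrate dots are rejected.
#'
#' @param text A single formula string.
#' @return An object of class `mol_formula`: a named integer vector of
#'   element counts (every count >= 1) with the original string in the
#'   `source_text` attribute.
#' @examples
#' parse_formula("C8F17KO3S")
#' parse_formula("H2O")
#' @seealso [format_formula()], [compute_dbe()], [heteroatom_profile()]
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  counts <- .parse_counts(text)
  structure(counts, source_text = text, class = "mol_formula")
}

.as_counts <- function(f) {
  if (inherits(f, "mol_formula")) {
    c(unclass(f))
  } else if (is.character(f) && length(f) == 1L) {
    .parse_counts(f)
  } else if (is.numeric(f) && !is.null(names(f))) {
    stopifnot(all(f >= 1), all(f == as.integer(f)),
              all(names(f) %in% .ELEMENTS))
    ints <- as.integer(f)
    names(ints) <- names(f)
    ints
  } else {
    stop("expected a mol_formula, a formula string, or a named count vector",
         call. = FALSE)
  }
}

.count_of <- function(counts, element) {
  if (element %in% names(counts)) counts[[element]] else 0L
}

#' Render a molecular formula in canonical Hill order
#'
#' Carbon first, hydrogen second when carbon is present, then the remaining
#' elements alphabetically; for carbon-free formulas all elements sort
#' alphabetically. Counts of one are omitted. The Hill string is the
#' canonical key used for formula-set membership throughout the package.
#'
#' @param f A `mol_formula`, a formula string, or a named count vector.
#' @return A single character string.
#' @examples
#' format_formula(parse_formula("O3SC8KF17"))  # "C8F17KO3S"
#' format_formula("H2O")
#' @export
format_formula <- function(f) {
  counts <- .as_counts(f)
  syms <- names(counts)
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")))
    ord <- c("C", if ("H" %in% syms) "H", rest)
  } else {
    ord <- sort(syms)
  }
  paste0(vapply(ord, function(s) {
    k <- counts[[s]]
    if (k == 1L) s else paste0(s, k)
  }, character(1)), collapse = "")
}

#' Canonicalize formula strings (vectorized)
#'
#' Parses and re-renders each formula in Hill order. Unparseable entries
#' yield `NA` rather than an error, so the result can be used directly as a
#' membership key over a feature table.
#'
#' @param texts Character vector of formula strings.
#' @return Character vector of Hill-order strings, `NA` where parsing failed.
#' @export
canonical_formula <- function(texts) {
  vapply(texts, function(t) {
    if (is.na(t)) return(NA_character_)
    tryCatch(format_formula(.parse_counts(t)), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
}

#' Double bond equivalents of a molecular formula
#'
#' Computes the degree of unsaturation DBE = C - (H + X)/2 + N/2 + 1, where
#' X is the total halogen count (F, Cl, Br, I) and O, S, P contribute
#' nothing. The arithmetic is exact: twice the DBE is an integer, so
#' half-integer values (radical or adduct species) are reported as-is. A
#' formula containing any element outside {C, H, N, O, S, P, F, Cl, Br, I}
#' has no defined DBE and is returned as excluded rather than as an error.
#'
#' @param f A `mol_formula`, a formula string, or a named count vector.
#' @return A list of class `dbe_result` with fields `value` (numeric, `NA`
#'   when excluded), `excluded` (logical) and `reason` (`NA` or the
#'   offending element symbols).
#' @examples
#' compute_dbe("C33H35FN2O5")  # 17
#' compute_dbe("C8F17KO3S")    # excluded: contains K
#' @export
compute_dbe <- function(f) {
  counts <- .as_counts(f)
  alien <- setdiff(names(counts), .DBE_COMPATIBLE)
  if (length(alien) > 0) {
    return(structure(
      list(value = NA_real_, excluded = TRUE,
           reason = paste0("incompatible element(s): ",
                           paste(sort(alien), collapse = ", "))),
      class = "dbe_result"))
  }
  x <- sum(vapply(.HALOGENS, .count_of, integer(1), counts = counts))
  twice <- 2L * .count_of(counts, "C") - (.count_of(counts, "H") + x) +
    .count_of(counts, "N") + 2L
  structure(list(value = twice / 2, excluded = FALSE, reason = NA_character_),
            class = "dbe_result")
}

#' @export
print.dbe_result <- function(x, ...) {
  if (x$excluded) {
    cat("DBE: excluded (", x$reason, ")\n", sep = "")
  } else {
    cat("DBE:", x$value, "\n")
  }
  invisible(x)
}

#' Vectorized DBE over formula strings
#'
#' @param texts Character vector of formula strings.
#' @return Numeric vector; `NA` for excluded or unparseable formulas.
#' @export
dbe_values <- function(texts) {
  vapply(texts, function(t) {
    if (is.na(t)) return(NA_real_)
    r <- tryCatch(compute_dbe(.parse_counts(t)), error = function(e) NULL)
    if (is.null(r) || r$excluded) NA_real_ else r$value
  }, numeric(1), USE.NAMES = FALSE)
}

#' Van Krevelen coordinates of a molecular formula
#'
#' Elemental H/C and O/C ratios, the axes of the Van Krevelen diagram used
#' to map compound-class regions of chemical space (lipids at high H/C and
#' low O/C, aromatic polyphenols at low H/C, carbohydrates near H/C = 2,
#' O/C = 1). Undefined for carbon-free formulas, which are dropped from the
#' diagram and reported in a skipped count by callers.
#'
#' @param f A `mol_formula`, a formula string, or a named count vector.
#' @param superclass_label Optional chemical superclass label (e.g. a
#'   ClassyFire superclass supplied with the annotations) carried along for
#'   plotting.
#' @return A list with `h_over_c`, `o_over_c` and `superclass_label`, or
#'   `NULL` when the formula contains no carbon.
#' @examples
#' van_krevelen("C18H32O2")  # linoleic acid: H/C 1.78, O/C 0.11
#' van_krevelen("H2O")       # NULL
#' @export
van_krevelen <- function(f, superclass_label = NULL) {
  counts <- .as_counts(f)
  cc <- .count_of(counts, "C")
  if (cc == 0L) {
    return(NULL)
  }
  list(h_over_c = .count_of(counts, "H") / cc,
       o_over_c = .count_of(counts, "O") / cc,
       superclass_label = superclass_label)
}

#' Van Krevelen table for a feature set (vectorized)
#'
#' @param formulas Character vector of formula strings.
#' @param superclass Optional character vector of superclass labels, recycled
#'   against `formulas`.
#' @return A tibble with columns `formula`, `h_over_c`, `o_over_c`,
#'   `superclass`; carbon-free or unparseable formulas are omitted and their
#'   number recorded in the `n_skipped` attribute.
#' @export
van_krevelen_table <- function(formulas, superclass = NULL) {
  if (is.null(superclass)) superclass <- NA_character_
  superclass <- rep_len(superclass, length(formulas))
  rows <- lapply(seq_along(formulas), function(i) {
    counts <- tryCatch(.parse_counts(formulas[[i]]), error = function(e) NULL)
    if (is.null(counts) || .count_of(counts, "C") == 0L) return(NULL)
    tibble::tibble(formula = formulas[[i]],
                   h_over_c = .count_of(counts, "H") / .count_of(counts, "C"),
                   o_over_c = .count_of(counts, "O") / .count_of(counts, "C"),
                   superclass = superclass[[i]])
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- dplyr::bind_rows(rows[keep])
  if (nrow(out) == 0) {
    out <- tibble::tibble(formula = character(), h_over_c = numeric(),
                          o_over_c = numeric(), superclass = character())
  }
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Heteroatom and halogen profile of a molecular formula
#'
#' Extracts the counts of the six tracked heteroatoms (S, P, F, Cl, Br, I)
#' directly from the parsed formula, plus a flag for the presence of any
#' halogen. Used to characterize the chemical signature of the putative
#' xenobiotic feature pool.
#'
#' @param f A `mol_formula`, a formula string, or a named count vector.
#' @return A list of class `heteroatom_profile` with `counts` (named integer
#'   vector over S, P, F, Cl, Br, I), `flags` (named logical) and
#'   `halogen_any`.
#' @examples
#' heteroatom_profile("C8F17KO3S")
#' @export
heteroatom_profile <- function(f) {
  counts <- .as_counts(f)
  het <- vapply(.HETEROATOMS, .count_of, integer(1), counts = counts)
  structure(list(counts = het, flags = het >= 1L,
                 halogen_any = any(het[.HALOGENS] >= 1L)),
            class = "heteroatom_profile")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula>", format_formula(x), "\n")
  invisible(x)
}
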