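#' Monoisotopic atom weights
#'
#' Monoisotopic masses (Da) of the elements occurring in phosphatidylcholine
#' (PC) and sphingomyelin (SM) sum formulas. `13C` is carried as a distinct
#' element so that first-isotope SM peaks (`[13C1]SM`) can be handled by plain
#' formula algebra.
#'
#' @return named numeric vector of monoisotopic masses in Da.
#' @examples
#' atom_weights()[["H"]]
#' @export
atom_weights <- function() {
  c(H = 1.007825, C = 12.000000, `13C` = 13.003355,
    O = 15.994915, N = 14.003074, P = 30.973762)
}

# elements recognised in sum formulas, in canonical order
.FORMULA_ELEMENTS <- c("C", "13C", "H", "N", "O", "P")

new_sum_formula <- function(counts) {
  out <- stats::setNames(integer(length(.FORMULA_ELEMENTS)), .FORMULA_ELEMENTS)
  out[names(counts)] <- as.integer(counts)
  structure(out, class = "sum_formula")
}

#' Subtract two sum formulas
#'
#' @param a,b objects of class `sum_formula` (or named integer vectors).
#' @return a named integer vector of signed element-count differences
#'   (`a - b`); entries may be negative.
#' @examples
#' formula_subtract(sum_formula(parse_lipid_name("PC O-33:0")),
#'                  sum_formula(parse_lipid_name("PC 32:0")))
#' @export
formula_subtract <- function(a, b) {
  elems <- union(names(a), names(b))
  av <- stats::setNames(integer(length(elems)), elems)
  bv <- av
  av[names(a)] <- a
  bv[names(b)] <- b
  d <- av - bv
  class(d) <- NULL
  d
}

#' @export
print.sum_formula <- function(x, ...) {
  nz <- x[x != 0]
  parts <- paste0(names(nz), ifelse(nz == 1, "", nz))
  cat("<sum formula> ", paste(parts, collapse = " "), "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Lipid entities

new_fatty_acyl <- function(carbons, double_bonds, bond = "acyl") {
  abort_if(carbons < 1 || carbons != round(carbons),
           "chain carbon count must be a positive integer, got %s", carbons)
  abort_if(double_bonds < 0 || double_bonds != round(double_bonds),
           "chain double-bond count must be a non-negative integer, got %s",
           double_bonds)
  abort_if(!bond %in% c("acyl", "alkyl"), "unknown bond type '%s'", bond)
  list(carbons = as.integer(carbons), double_bonds = as.integer(double_bonds),
       bond = bond)
}

#' Construct a lipid entity
#'
#' Low-level constructor behind [parse_lipid_name()]. A lipid entity records a
#' PC or SM at one of three resolutions: `sum_level` (kit-style bulk measure),
#' `species_level` (total carbons and double bonds only), or
#' `fatty_acid_level` (both side-chains resolved, sn-positions unknown).
#'
#' @param lipid_class `"PC"` or `"SM"`.
#' @param resolution one of `"sum_level"`, `"species_level"`,
#'   `"fatty_acid_level"`.
#' @param total_carbons,total_double_bonds totals over both chains (x, y).
#' @param chains for `fatty_acid_level`, a list of two fatty acyl descriptors
#'   as produced internally (carbons, double_bonds, bond).
#' @param ether `TRUE` if one chain is alkyl-bound (PC-O / "ae").
#' @param isotope_label `"none"` or `"13C1"` (SM first-isotope peak only).
#' @param kit_annotation optional original kit label text.
#' @return an object of class `lipid_entity`.
#' @export
lipid_entity <- function(lipid_class, resolution, total_carbons,
                         total_double_bonds, chains = NULL, ether = FALSE,
                         isotope_label = "none", kit_annotation = NULL) {
  abort_if(!lipid_class %in% c("PC", "SM"), "unsupported lipid class '%s'",
           lipid_class)
  abort_if(!resolution %in% c("sum_level", "species_level", "fatty_acid_level"),
           "unknown resolution '%s'", resolution)
  abort_if(total_carbons < 1 || total_carbons != round(total_carbons),
           "total carbons must be a positive integer, got %s", total_carbons)
  abort_if(total_double_bonds < 0 ||
             total_double_bonds != round(total_double_bonds),
           "total double bonds must be a non-negative integer, got %s",
           total_double_bonds)
  abort_if(isotope_label == "13C1" && lipid_class != "SM",
           "isotope label 13C1 is only modelled for SM")
  if (!is.null(chains)) {
    abort_if(resolution != "fatty_acid_level",
             "chains may only be given at fatty_acid_level")
    abort_if(length(chains) != 2L, "exactly two chains required")
    cx <- sum(vapply(chains, `[[`, integer(1), "carbons"))
    cy <- sum(vapply(chains, `[[`, integer(1), "double_bonds"))
    abort_if(cx != total_carbons,
             "chain carbons (%d) do not sum to total carbons (%d)",
             cx, total_carbons)
    abort_if(cy != total_double_bonds,
             "chain double bonds (%d) do not sum to total (%d)",
             cy, total_double_bonds)
    n_alkyl <- sum(vapply(chains, `[[`, character(1), "bond") == "alkyl")
    abort_if(n_alkyl > 1L, "at most one alkyl chain per lipid")
    abort_if(ether != (n_alkyl == 1L),
             "ether flag inconsistent with chain bond types")
    chains <- canonical_chain_order(chains)
  } else {
    abort_if(resolution == "fatty_acid_level",
             "fatty_acid_level entities require chains")
  }
  structure(list(lipid_class = lipid_class, resolution = resolution,
                 total_carbons = as.integer(total_carbons),
                 total_double_bonds = as.integer(total_double_bonds),
                 chains = chains, ether = isTRUE(ether),
                 isotope_label = isotope_label,
                 kit_annotation = kit_annotation),
            class = "lipid_entity")
}

# alkyl chain first; otherwise ascending by (carbons, double_bonds)
canonical_chain_order <- function(chains) {
  key <- vapply(chains, function(ch) {
    (ch$bond != "alkyl") * 1e8 + ch$carbons * 1e3 + ch$double_bonds
  }, numeric(1))
  chains[order(key)]
}

#' @export
print.lipid_entity <- function(x, ...) {
  dialect <- switch(x$resolution, sum_level = "kit",
                    species_level = "species", fatty_acid_level = "fatty_acid")
  cat("<lipid entity> ", format_lipid_name(x, dialect),
      " [", x$resolution, "]\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Parsing

# normalise unicode hyphen/minus variants and whitespace
normalise_label <- function(label) {
  label <- gsub("[‐‑‒–—−]", "-", label)
  label <- gsub("\\s+", " ", label)
  trimws(label)
}

parse_int_pair <- function(cs, ds, label) {
  c(as.integer(cs), as.integer(ds))
}

#' Parse a lipid shorthand label
#'
#' Understands three dialects of PC/SM shorthand:
#' \describe{
#'   \item{kit sum}{`"PC aa Cx:y"`, `"PC ae Cx:y"` (bulk species-level kit
#'     measures; `aa` diacyl, `ae` acyl-alkyl)}
#'   \item{species}{`"PC x:y"`, `"PC O-x:y"`, `"SM x:y"`, `"[13C1]SM x:y"`}
#'   \item{fatty acid}{`"PC x1:y1_x2:y2"`, `"PC O-x1:y1_x2:y2"` (the `O-`
#'     chain is the alkyl-bound one)}
#' }
#' Parsing is whitespace-tolerant and accepts typographic hyphen variants.
#'
#' @param label character vector of labels.
#' @return a `lipid_entity` for a single label, otherwise a list of them.
#' @examples
#' parse_lipid_name("PC aa C36:2")
#' parse_lipid_name("PC 18:0_18:2")
#' @export
parse_lipid_name <- function(label) {
  if (length(label) > 1L) return(lapply(label, parse_lipid_name))
  abort_if(!is.character(label) || is.na(label), "label must be a string")
  raw <- label
  s <- normalise_label(label)

  num <- "(\\d+)"
  # kit sum: PC aa Cx:y / PC ae Cx:y
  m <- regmatches(s, regexec(paste0("^PC (aa|ae) ?C", num, ":", num, "$"), s))[[1]]
  if (length(m)) {
    x <- as.integer(m[3]); y <- as.integer(m[4])
    return(lipid_entity("PC", "sum_level", x, y, ether = m[2] == "ae",
                        kit_annotation = raw))
  }
  # fatty-acid level: PC x1:y1_x2:y2 (optionally O- first chain)
  m <- regmatches(s, regexec(paste0("^PC (O-)?", num, ":", num, "_",
                                    num, ":", num, "$"), s))[[1]]
  if (length(m)) {
    ether <- m[2] == "O-"
    ch1 <- new_fatty_acyl(as.integer(m[3]), as.integer(m[4]),
                          if (ether) "alkyl" else "acyl")
    ch2 <- new_fatty_acyl(as.integer(m[5]), as.integer(m[6]), "acyl")
    return(lipid_entity("PC", "fatty_acid_level",
                        ch1$carbons + ch2$carbons,
                        ch1$double_bonds + ch2$double_bonds,
                        chains = list(ch1, ch2), ether = ether))
  }
  # species level: PC x:y / PC O-x:y. Totals in the single-fatty-acid range
  # are rejected: "PC 16:0" is almost certainly an incomplete fatty-acid
  # label (one chain missing), not a 16-carbon species.
  m <- regmatches(s, regexec(paste0("^PC (O-)?", num, ":", num, "$"), s))[[1]]
  if (length(m)) {
    x <- as.integer(m[3])
    abort_if(x <= 22L,
             "cannot parse lipid label '%s': total of %d carbons is in the single-chain range; species-level PC labels need both chains (use 'PC x1:y1_x2:y2' for fatty-acid resolution)",
             raw, x)
    return(lipid_entity("PC", "species_level", x, as.integer(m[4]),
                        ether = m[2] == "O-"))
  }
  # SM species, optionally 13C1-labelled
  m <- regmatches(s, regexec(paste0("^(\\[13C1\\] ?)?SM ?", num, ":", num, "$"),
                             s))[[1]]
  if (length(m)) {
    return(lipid_entity("SM", "species_level", as.integer(m[3]),
                        as.integer(m[4]),
                        isotope_label = if (nzchar(m[2])) "13C1" else "none"))
  }
  stop(sprintf("cannot parse lipid label '%s': not a recognised kit, species or fatty-acid shorthand",
               raw), call. = FALSE)
}

#' Format a lipid entity as shorthand text
#'
#' Inverse of [parse_lipid_name()]. Chains are emitted in canonical order
#' (alkyl chain first, then ascending by carbons and double bonds), so
#' formatting a parsed canonical label is the identity.
#'
#' @param entity a `lipid_entity`.
#' @param dialect `"kit"`, `"species"` or `"fatty_acid"`.
#' @return a character label.
#' @examples
#' format_lipid_name(parse_lipid_name("PC aa C36:2"), "kit")
#' @export
format_lipid_name <- function(entity, dialect = c("kit", "species",
                                                  "fatty_acid")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(entity, "lipid_entity"))
  x <- entity$total_carbons; y <- entity$total_double_bonds
  if (dialect == "kit") {
    abort_if(entity$lipid_class != "PC", "kit dialect is defined for PC only")
    return(sprintf("PC %s C%d:%d", if (entity$ether) "ae" else "aa", x, y))
  }
  if (dialect == "species") {
    if (entity$lipid_class == "SM") {
      pre <- if (entity$isotope_label == "13C1") "[13C1]SM" else "SM"
      return(sprintf("%s %d:%d", pre, x, y))
    }
    return(sprintf("PC %s%d:%d", if (entity$ether) "O-" else "", x, y))
  }
  # fatty_acid dialect
  abort_if(entity$resolution != "fatty_acid_level",
           "fatty_acid dialect requires a fatty_acid_level entity")
  ch <- canonical_chain_order(entity$chains)
  pre <- if (ch[[1]]$bond == "alkyl") "O-" else ""
  sprintf("PC %s%d:%d_%d:%d", pre, ch[[1]]$carbons, ch[[1]]$double_bonds,
          ch[[2]]$carbons, ch[[2]]$double_bonds)
}

# ---------------------------------------------------------------------------
# Sum formulas and masses

#' Sum formula of a PC or SM species
#'
#' Neutral-molecule sum formulas follow standard glycerophosphocholine and
#' sphingomyelin chemistry: a diacyl PC x:y is C(x+8) H(2x-2y+16) N O8 P, an
#' ether (acyl-alkyl) PC gains 2 H and loses one O, and an SM x:y is C(x+5)
#' H(2x-2y+13) N2 O6 P. A `13C1` isotope label replaces one C by one 13C.
#'
#' @param entity a `lipid_entity` at species or fatty-acid resolution (or a
#'   label string, parsed first).
#' @return an object of class `sum_formula` (named integer element counts).
#' @examples
#' sum_formula(parse_lipid_name("PC 30:0"))
#' @export
sum_formula <- function(entity) {
  if (is.character(entity)) entity <- parse_lipid_name(entity)
  stopifnot(inherits(entity, "lipid_entity"))
  abort_if(entity$resolution == "sum_level",
           "sum formulas are defined for species- or fatty-acid-level entities; resolve the kit sum to a species first")
  x <- entity$total_carbons; y <- entity$total_double_bonds
  if (entity$lipid_class == "PC") {
    counts <- c(C = x + 8L, H = 2L * x - 2L * y + 16L, N = 1L, O = 8L, P = 1L)
    if (entity$ether) {
      counts[["H"]] <- counts[["H"]] + 2L
      counts[["O"]] <- counts[["O"]] - 1L
    }
  } else {
    counts <- c(C = x + 5L, H = 2L * x - 2L * y + 13L, N = 2L, O = 6L, P = 1L)
  }
  if (identical(entity$isotope_label, "13C1")) {
    counts[["C"]] <- counts[["C"]] - 1L
    counts <- c(counts, `13C` = 1L)
  }
  abort_if(counts[["H"]] < 0L,
           "unphysical composition %d:%d (negative hydrogen count)", x, y)
  new_sum_formula(counts)
}

#' Monoisotopic mass of a sum formula
#'
#' @param formula a `sum_formula`, a named integer vector of element counts,
#'   or a `lipid_entity`/label (converted via [sum_formula()]).
#' @param weights named vector of monoisotopic atom weights in Da; defaults to
#'   [atom_weights()].
#' @return mass in Da.
#' @examples
#' monoisotopic_mass(sum_formula(parse_lipid_name("PC 30:0")))
#' @export
monoisotopic_mass <- function(formula, weights = atom_weights()) {
  if (is.character(formula) || inherits(formula, "lipid_entity")) {
    formula <- sum_formula(formula)
  }
  unknown <- setdiff(names(formula)[formula != 0], names(weights))
  abort_if(length(unknown) > 0, "unknown element(s) in formula: %s",
           paste(unknown, collapse = ", "))
  sum(unclass(formula) * weights[names(formula)])
}

#' Nominal (integer) neutral mass
#'
#' Defined as the floor of the monoisotopic neutral mass, matching the
#' parenthesised masses conventionally printed next to species labels
#' (e.g. "PC 30:0 (705)").
#'
#' @inheritParams monoisotopic_mass
#' @return integer nominal mass.
#' @export
nominal_mass <- function(formula, weights = atom_weights()) {
  as.integer(floor(monoisotopic_mass(formula, weights)))
}

# delta sum formulas of the eight isobar rules (relative to the anchor)
.ISOBAR_RULES <- list(
  # anchored at diacyl PC x:y
  pc_plus1_plus7  = c(C = 1, H = -12),             # +CH2 -14H
  pcO_plus1       = c(C = 1, H = 4, O = -1),       # +CH2 +2H -O
  pcO_plus2_plus7 = c(C = 2, H = -8, O = -1),      # +2(CH2) -12H -O
  sm13C_plus4     = c(`13C` = 1, H = 5, N = 1, O = -2),
  # anchored at ether PC O-x:y
  pcO_plus1_plus7 = c(C = 1, H = -12),
  pc_minus1       = c(C = -1, H = -4, O = 1),      # +O -CH2 -2H
  pc_plus7        = c(O = 1, H = -16),
  sm13C_plus3     = c(N = 1, H = 1, `13C` = 1, C = -1, O = -1)
)

#' Mass delta of an isobar rule
#'
#' Isobaric neighbours of a PC species within typical triple-quadrupole mass
#' resolution differ from the anchor by small fixed mass deltas that are
#' independent of chain length and desaturation. Rules anchored at a diacyl
#' PC x:y: `pc_plus1_plus7` (PC x+1:y+7), `pcO_plus1` (PC O-x+1:y),
#' `pcO_plus2_plus7` (PC O-x+2:y+7), `sm13C_plus4` ([13C1]SM x+4:y). Rules
#' anchored at an ether PC O-x:y: `pcO_plus1_plus7`, `pc_minus1`, `pc_plus7`,
#' `sm13C_plus3`.
#'
#' @param rule rule identifier (see Details); vectorised.
#' @param weights monoisotopic atom weights.
#' @return signed mass delta(s) in Da.
#' @examples
#' mass_delta("pc_plus1_plus7")   # -0.0939 Da
#' @export
mass_delta <- function(rule, weights = atom_weights()) {
  if (length(rule) > 1L) {
    return(vapply(rule, mass_delta, numeric(1), weights = weights))
  }
  abort_if(!rule %in% names(.ISOBAR_RULES), "unknown isobar rule '%s'", rule)
  delta <- .ISOBAR_RULES[[rule]]
  sum(delta * weights[names(delta)])
}
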