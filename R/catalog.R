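#' Chain enumeration constraints
#'
#' Bounds applied to each side-chain when enumerating the theoretically
#' possible fatty-acid-level constituents of a PC species.
#'
#' @param min_chain_carbons minimum carbons per chain (default 2).
#' @param max_chain_carbons maximum carbons per chain; `NULL` means the total
#'   minus `min_chain_carbons` (i.e. effectively unconstrained).
#' @param max_double_bonds_per_chain integer bound, or `"chemical"` for the
#'   structural limit `floor((carbons - 1) / 2)` per chain.
#' @param include_ether include acyl-alkyl (PC-O) isobars in catalogs.
#' @param include_sm_isotopologue include `[13C1]SM` first-isotope peaks for
#'   sums whose isobaric SM is not quantified by the kit.
#' @return an object of class `enumeration_constraints`.
#' @export
enumeration_constraints <- function(min_chain_carbons = 2L,
                                    max_chain_carbons = NULL,
                                    max_double_bonds_per_chain = "chemical",
                                    include_ether = TRUE,
                                    include_sm_isotopologue = TRUE) {
  abort_if(min_chain_carbons < 0, "min_chain_carbons must be >= 0")
  if (!is.null(max_chain_carbons)) {
    abort_if(max_chain_carbons < min_chain_carbons,
             "max_chain_carbons (%s) below min_chain_carbons (%s)",
             max_chain_carbons, min_chain_carbons)
  }
  if (!identical(max_double_bonds_per_chain, "chemical")) {
    abort_if(!is.numeric(max_double_bonds_per_chain) ||
               max_double_bonds_per_chain < 0,
             "max_double_bonds_per_chain must be 'chemical' or a count >= 0")
  }
  structure(list(min_chain_carbons = as.integer(min_chain_carbons),
                 max_chain_carbons = if (!is.null(max_chain_carbons))
                   as.integer(max_chain_carbons),
                 max_double_bonds_per_chain = max_double_bonds_per_chain,
                 include_ether = isTRUE(include_ether),
                 include_sm_isotopologue = isTRUE(include_sm_isotopologue)),
            class = "enumeration_constraints")
}

# per-chain double-bond bound under the constraints
chain_db_bound <- function(carbons, constraints) {
  if (identical(constraints$max_double_bonds_per_chain, "chemical")) {
    pmax(0L, floor((carbons - 1) / 2))
  } else {
    rep(as.integer(constraints$max_double_bonds_per_chain), length(carbons))
  }
}

#' Enumerate chain splits of a PC species
#'
#' Systematically distributes `x` total carbons and `y` total double bonds
#' over two side-chains, returning every unordered admissible pair. For ether
#' species (`ether = TRUE`) the first chain is the alkyl one; assignments that
#' differ only in which chain carries the ether bond count as distinct
#' molecules unless the two chains are identical.
#'
#' @param x total carbon count.
#' @param y total double-bond count.
#' @param constraints an [enumeration_constraints()] object.
#' @param ether enumerate acyl-alkyl pairs instead of diacyl pairs.
#' @return data frame with columns `c1`, `d1`, `c2`, `d2` (canonical chain
#'   order) — zero rows when the constraints are infeasible.
#' @examples
#' enumerate_chain_pairs(32, 1)
#' @export
enumerate_chain_pairs <- function(x, y, constraints = enumeration_constraints(),
                                  ether = FALSE) {
  x <- as.integer(x); y <- as.integer(y)
  cmin <- constraints$min_chain_carbons
  cmax <- if (is.null(constraints$max_chain_carbons)) x - cmin else
    min(constraints$max_chain_carbons, x - cmin)
  empty <- data.frame(c1 = integer(), d1 = integer(),
                      c2 = integer(), d2 = integer())
  if (x < 2L * cmin || cmax < cmin) return(empty)

  rows <- list()
  for (c1 in seq.int(cmin, cmax)) {
    c2 <- x - c1
    if (c2 < cmin || c2 > cmax) next
    if (!ether && c1 > c2) next  # unordered diacyl pairs: canonical c1 <= c2
    b1 <- chain_db_bound(c1, constraints)
    b2 <- chain_db_bound(c2, constraints)
    d1 <- seq.int(0L, min(b1, y))
    d1 <- d1[(y - d1) <= b2]
    if (!ether && c1 == c2) d1 <- d1[d1 <= y - d1]  # symmetric split dedupe
    if (length(d1)) {
      rows[[length(rows) + 1L]] <-
        data.frame(c1 = c1, d1 = d1, c2 = c2, d2 = y - d1)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# build fatty-acid-level entities from an enumeration data frame
pairs_to_entities <- function(pairs, ether = FALSE) {
  lapply(seq_len(nrow(pairs)), function(i) {
    ch1 <- new_fatty_acyl(pairs$c1[i], pairs$d1[i],
                          if (ether) "alkyl" else "acyl")
    ch2 <- new_fatty_acyl(pairs$c2[i], pairs$d2[i], "acyl")
    lipid_entity("PC", "fatty_acid_level", pairs$c1[i] + pairs$c2[i],
                 pairs$d1[i] + pairs$d2[i], chains = list(ch1, ch2),
                 ether = ether)
  })
}

# TRUE if the species-level member has a physically possible formula
member_feasible <- function(x, y, ether) {
  x >= 2L && y >= 0L && (2L * x - 2L * y + 16L + if (ether) 2L else 0L) >= 0L
}

#' Isobaric series of a PC species
#'
#' Lists the species-level compounds indistinguishable from the anchor within
#' typical kit mass resolution. For a diacyl anchor PC x:y these are
#' PC x+1:y+7, PC O-x+1:y and PC O-x+2:y+7; for an ether anchor PC O-x:y they
#' are PC O-x+1:y+7, PC x-1:y and PC x:y+7. The first-isotope sphingomyelin
#' peak ([13C1]SM x+4:y, resp. x+3:y) is appended unless the corresponding SM
#' is quantified (and hence isotope-corrected) by the kit. Members with
#' unphysical implied element counts are dropped.
#'
#' @param sum_entity a PC entity at sum or species level, or a label string.
#' @param kit_quantified_sms character vector of SM species labels quantified
#'   by the kit (e.g. `"SM 36:0"`).
#' @param include_sm_isotopologue consider the SM first-isotope peak at all.
#' @return a list of species-level `lipid_entity` objects; each carries the
#'   generating rule in `attr(, "rule")` (`"anchor"` for the anchor itself).
#' @examples
#' sapply(isobaric_series("PC 32:0"), format_lipid_name, dialect = "species")
#' @export
isobaric_series <- function(sum_entity, kit_quantified_sms = character(),
                            include_sm_isotopologue = TRUE) {
  if (is.character(sum_entity)) sum_entity <- parse_lipid_name(sum_entity)
  abort_if(sum_entity$lipid_class != "PC",
           "isobaric series are defined for PC/PC-O anchors only")
  x <- sum_entity$total_carbons; y <- sum_entity$total_double_bonds
  ether <- sum_entity$ether

  sm_canonical <- if (length(kit_quantified_sms)) {
    vapply(kit_quantified_sms,
           function(l) format_lipid_name(parse_lipid_name(l), "species"),
           character(1))
  } else character()

  members <- list(list(x = x, y = y, ether = ether, rule = "anchor"))
  if (!ether) {
    members <- c(members, list(
      list(x = x + 1L, y = y + 7L, ether = FALSE, rule = "pc_plus1_plus7"),
      list(x = x + 1L, y = y,      ether = TRUE,  rule = "pcO_plus1"),
      list(x = x + 2L, y = y + 7L, ether = TRUE,  rule = "pcO_plus2_plus7")))
    sm_x <- x + 4L; sm_rule <- "sm13C_plus4"
  } else {
    members <- c(members, list(
      list(x = x + 1L, y = y + 7L, ether = TRUE,  rule = "pcO_plus1_plus7"),
      list(x = x - 1L, y = y,      ether = FALSE, rule = "pc_minus1"),
      list(x = x,      y = y + 7L, ether = FALSE, rule = "pc_plus7")))
    sm_x <- x + 3L; sm_rule <- "sm13C_plus3"
  }

  out <- list()
  for (m in members) {
    if (!member_feasible(m$x, m$y, m$ether)) next
    e <- lipid_entity("PC", "species_level", m$x, m$y, ether = m$ether)
    attr(e, "rule") <- m$rule
    out[[length(out) + 1L]] <- e
  }
  if (include_sm_isotopologue && sm_x >= 1L &&
      (2L * sm_x - 2L * y + 13L) >= 0L) {
    sm_label <- sprintf("SM %d:%d", sm_x, y)
    if (!sm_label %in% sm_canonical) {
      e <- lipid_entity("SM", "species_level", sm_x, y,
                        isotope_label = "13C1")
      attr(e, "rule") <- sm_rule
      out[[length(out) + 1L]] <- e
    }
  }
  out
}

#' Assemble constituent catalogs for kit PC sums
#'
#' For each kit-style PC sum label, enumerates every theoretically possible
#' isobaric fatty-acid-level constituent (over the full isobaric series of the
#' sum) and maps the measured fatty-acid-level analytes onto the sums. Each
#' measured analyte must map to exactly one sum across the whole catalog set.
#'
#' @param kit_labels character vector of sum labels (kit dialect
#'   `"PC aa Cx:y"` / `"PC ae Cx:y"`, or species labels of the same entities).
#' @param measured_analytes character vector of fatty-acid-level labels
#'   available on the side-chain resolving platform.
#' @param constraints an [enumeration_constraints()] object.
#' @param kit_quantified_sms SM species labels quantified (isotope-corrected)
#'   by the kit.
#' @return an object of class `constituent_catalog_set`: a named list of
#'   `constituent_catalog` objects with fields `sum_label`, `sum_entity`,
#'   `table` (constituent, rule, mass_delta_da, measured) and `measured`.
#' @examples
#' cats <- assemble_constituent_catalog("PC aa C36:2",
#'   measured_analytes = c("PC 16:0_20:2", "PC 18:0_18:2", "PC 18:1_18:1"))
#' cats[["PC aa C36:2"]]$measured
#' @export
assemble_constituent_catalog <- function(kit_labels,
                                         measured_analytes = character(),
                                         constraints = enumeration_constraints(),
                                         kit_quantified_sms = character()) {
  sums <- lapply(kit_labels, function(l) {
    e <- parse_lipid_name(l)
    abort_if(e$lipid_class != "PC", "kit label '%s' is not a PC", l)
    e
  })
  sum_labels <- vapply(sums, format_lipid_name, character(1), dialect = "kit")
  abort_if(anyDuplicated(sum_labels) > 0, "duplicate kit sum labels")

  catalogs <- vector("list", length(sums))
  names(catalogs) <- sum_labels
  for (k in seq_along(sums)) {
    anchor <- lipid_entity("PC", "species_level", sums[[k]]$total_carbons,
                           sums[[k]]$total_double_bonds,
                           ether = sums[[k]]$ether)
    series <- isobaric_series(
      anchor, kit_quantified_sms,
      include_sm_isotopologue = constraints$include_sm_isotopologue)
    rows <- list()
    for (member in series) {
      rule <- attr(member, "rule")
      delta <- if (rule == "anchor") 0 else mass_delta(rule)
      if (member$lipid_class == "SM") {
        rows[[length(rows) + 1L]] <- data.frame(
          constituent = format_lipid_name(member, "species"),
          rule = rule, mass_delta_da = delta, stringsAsFactors = FALSE)
        next
      }
      if (member$ether && !constraints$include_ether) next
      pairs <- enumerate_chain_pairs(member$total_carbons,
                                     member$total_double_bonds,
                                     constraints, ether = member$ether)
      if (!nrow(pairs)) next
      ents <- pairs_to_entities(pairs, ether = member$ether)
      rows[[length(rows) + 1L]] <- data.frame(
        constituent = vapply(ents, format_lipid_name, character(1),
                             dialect = "fatty_acid"),
        rule = rule, mass_delta_da = delta, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    abort_if(anyDuplicated(tab$constituent) > 0,
             "internal error: duplicate constituents in catalog for %s",
             sum_labels[k])
    tab$measured <- FALSE
    catalogs[[k]] <- structure(
      list(sum_label = sum_labels[k], sum_entity = sums[[k]], table = tab,
           measured = character()),
      class = "constituent_catalog")
  }

  # map measured analytes: each must land in exactly one catalog
  if (length(measured_analytes)) {
    canon <- vapply(measured_analytes, function(l) {
      e <- parse_lipid_name(l)
      abort_if(e$resolution != "fatty_acid_level",
               "measured analyte '%s' is not at fatty-acid resolution", l)
      format_lipid_name(e, "fatty_acid")
    }, character(1), USE.NAMES = FALSE)
    abort_if(anyDuplicated(canon) > 0, "duplicate measured analytes")
    hits <- lapply(canon, function(a) {
      which(vapply(catalogs, function(ct) a %in% ct$table$constituent,
                   logical(1)))
    })
    n_hits <- lengths(hits)
    bad <- canon[n_hits != 1L]
    abort_if(length(bad) > 0,
             "measured analyte(s) mapping to zero or multiple sums: %s",
             paste(bad, collapse = ", "))
    for (i in seq_along(canon)) {
      k <- hits[[i]]
      ct <- catalogs[[k]]
      ct$table$measured[ct$table$constituent == canon[i]] <- TRUE
      ct$measured <- c(ct$measured, canon[i])
      catalogs[[k]] <- ct
    }
  }
  structure(catalogs, class = "constituent_catalog_set")
}

#' @export
print.constituent_catalog <- function(x, ...) {
  cat(sprintf("<constituent catalog> %s: %d theoretical, %d measured\n",
              x$sum_label, nrow(x$table), length(x$measured)))
  invisible(x)
}

#' @export
print.constituent_catalog_set <- function(x, ...) {
  cat(sprintf("<constituent catalog set> %d PC sums\n", length(x)))
  for (ct in x) print(ct)
  invisible(x)
}

#' Flatten a catalog set to a data frame
#'
#' One row per (sum label, constituent) with the generating isobar rule, its
#' mass delta from the anchor (Da), and the measured flag — the export schema
#' for delimited text.
#'
#' @param x a `constituent_catalog_set`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return a data frame.
#' @export
as.data.frame.constituent_catalog_set <- function(x, row.names = NULL,
                                                  optional = FALSE, ...) {
  out <- do.call(rbind, lapply(unclass(x), function(ct) {
    cbind(data.frame(sum_label = ct$sum_label, stringsAsFactors = FALSE),
          ct$table)
  }))
  rownames(out) <- NULL
  out
}
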