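# shared fixtures, all built in code

# brute-force chain-pair enumeration: independent double loop over (c1, d1)
brute_force_pairs <- function(x, y, cmin, cmax, dbmax = "chemical") {
  bound <- function(cc) {
    if (identical(dbmax, "chemical")) max(0, floor((cc - 1) / 2)) else dbmax
  }
  seen <- character()
  out <- list()
  for (c1 in seq_len(x)) {
    c2 <- x - c1
    if (c1 < cmin || c1 > cmax || c2 < cmin || c2 > cmax || c2 < 1) next
    for (d1 in 0:y) {
      d2 <- y - d1
      if (d1 > bound(c1) || d2 > bound(c2) || d2 < 0) next
      a <- c(c1, d1); b <- c(c2, d2)
      key <- if (a[1] < b[1] || (a[1] == b[1] && a[2] <= b[2])) {
        paste(a[1], a[2], b[1], b[2])
      } else {
        paste(b[1], b[2], a[1], a[2])
      }
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- key
      }
    }
  }
  if (!length(out)) character(0) else sort(unlist(out))
}

# sample one integer from cmin..cmax, safe for length-1 ranges
sample_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

pairs_as_keys <- function(pairs) {
  if (!nrow(pairs)) return(character())
  sort(paste(pairs$c1, pairs$d1, pairs$c2, pairs$d2))
}

# tiny paired matrices with explicit values; one sum, constituents given as
# a named list of per-sample concentration vectors
toy_matrices <- function(sum_label, sum_conc, constituents,
                         meta = NULL) {
  n <- length(sum_conc)
  ids <- sprintf("s%02d", seq_len(n))
  if (is.null(meta)) {
    meta <- data.frame(sample_id = ids,
                       subject = rep_len(c("A", "B"), n),
                       timepoint = sprintf("t%02d", seq_len(n)),
                       stringsAsFactors = FALSE)
  } else {
    meta$sample_id <- ids
  }
  sp <- matrix(sum_conc, ncol = 1, dimnames = list(ids, sum_label))
  fa <- do.call(cbind, constituents)
  rownames(fa) <- ids
  list(species = concentration_matrix(sp, meta, "species_level_kit"),
       fa = concentration_matrix(fa, meta, "fatty_acid_level"))
}

# catalog set for the default synthetic panel
panel_catalogs <- function(sums = default_sum_panel()) {
  assemble_constituent_catalog(
    vapply(sums, `[[`, character(1), "sum_label"),
    measured_analytes = unlist(lapply(sums, `[[`, "constituents")))
}
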