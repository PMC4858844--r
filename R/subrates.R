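AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Collapse recurrent missense substitutions to unique events
#'
#' Each distinct substitution is counted once per position: two records of
#' the same (isoform, position, reference, alternate) collapse to one,
#' while different alternate residues at the same position remain separate
#' events.
#'
#' @param mutations mutation data.table; only missense rows are used
#' @return data.table with `isoform_id`, `position`, `ref_aa`, `alt_aa`,
#'   one row per unique substitution event
#' @export
dedupe_substitutions <- function(mutations) {
  mutations <- data.table::as.data.table(mutations)
  mis <- mutations[mtype == "missense"]
  if (nrow(mis) == 0L) {
    return(data.table::data.table(isoform_id = character(0),
                                  position = integer(0),
                                  ref_aa = character(0),
                                  alt_aa = character(0)))
  }
  unique(mis[, .(isoform_id, position = start, ref_aa, alt_aa)])
}

new_substitution_matrix <- function(n, n_nonstandard = 0L) {
  N <- sum(n)
  R <- if (N > 0) n / N * 100 else n
  structure(list(n = n, N = N, R = R, n_nonstandard = n_nonstandard,
                 empty = N == 0),
            class = "SubstitutionMatrix")
}

#' @export
print.SubstitutionMatrix <- function(x, ...) {
  cat(sprintf("SubstitutionMatrix: %d unique substitutions", x$N))
  if (x$n_nonstandard > 0L) {
    cat(sprintf(" (+%d with nonstandard residues)", x$n_nonstandard))
  }
  cat("\n")
  if (x$N > 0) {
    top <- which(x$R == max(x$R), arr.ind = TRUE)[1, ]
    cat(sprintf("  most frequent: %s->%s (%.2f%%)\n",
                rownames(x$n)[top[1]], colnames(x$n)[top[2]],
                max(x$R)))
  }
  invisible(x)
}

count_matrix <- function(events) {
  n <- matrix(0L, 20L, 20L, dimnames = list(ref = AA20, alt = AA20))
  std <- events$ref_aa %in% AA20 & events$alt_aa %in% AA20 &
    events$ref_aa != events$alt_aa
  if (any(std)) {
    tab <- table(factor(events$ref_aa[std], AA20),
                 factor(events$alt_aa[std], AA20))
    n <- n + unclass(tab)
    dimnames(n) <- list(ref = AA20, alt = AA20)
  }
  new_substitution_matrix(n, n_nonstandard = sum(!std))
}

#' Amino-acid substitution percentages, optionally split by region
#'
#' Computes the 20x20 substitution percentage matrix
#' `R[i, j] = 100 * n[i, j] / N` over deduplicated missense events, where
#' `n[i, j]` counts substitutions of reference residue i to alternate j
#' and N is the total event count.  When regions are supplied the matrix
#' is computed separately for events at positions inside any region of
#' the same isoform and for the remaining events.  Substitutions
#' involving nonstandard residues (U, X, B, Z, ...) are excluded from the
#' matrix and tallied in `n_nonstandard`.
#'
#' @param events deduplicated events from [dedupe_substitutions()]
#' @param regions optional region data.table with `isoform_id`, `start`,
#'   `end`
#' @return a `SubstitutionMatrix` (fields `n`, `N`, `R`, `n_nonstandard`,
#'   `empty`); with regions, a list with elements `total`, `inside`,
#'   `outside`
#' @export
substitution_percentages <- function(events, regions = NULL) {
  events <- data.table::as.data.table(events)
  if (is.null(regions)) return(count_matrix(events))
  regions <- data.table::as.data.table(regions)
  inside <- rep(FALSE, nrow(events))
  if (nrow(events) && nrow(regions)) {
    inside <- protein_overlaps_any(
      events$isoform_id, events$position, events$position,
      regions$isoform_id, regions$start, regions$end
    )
  }
  list(total = count_matrix(events),
       inside = count_matrix(events[inside]),
       outside = count_matrix(events[!inside]))
}

#' Long-format view of a substitution matrix
#'
#' @param mat a `SubstitutionMatrix`
#' @param partition label stored in the `partition` column (e.g.
#'   `"inside"`)
#' @return data.table with `ref`, `alt`, `count`, `percent`, `partition`,
#'   nonzero rows only, sorted by decreasing percentage
#' @export
substitution_long <- function(mat, partition = "total") {
  idx <- which(mat$n > 0, arr.ind = TRUE)
  out <- data.table::data.table(
    ref = rownames(mat$n)[idx[, 1]],
    alt = colnames(mat$n)[idx[, 2]],
    count = mat$n[idx],
    percent = mat$R[idx],
    partition = partition
  )
  data.table::setorder(out, -percent, ref, alt)
  out[]
}
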