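#' Mutation-cleaning filters
#'
#' Four cohort-level cleaning steps applied in a fixed order before region
#' calling: hypermutated-sample removal, common-SNP exclusion, clonal
#' duplicate-sample collapse, and low-complexity overlap removal.  Each
#' filter returns the retained mutations together with an auditable
#' report.
#'
#' @name filters
NULL

filter_report <- function(filter_name, removed, parameters = list(),
                          removed_samples = character(0)) {
  list(filter_name = filter_name,
       removed_count = removed,
       removed_samples = removed_samples,
       parameters = parameters)
}

#' Discard all mutations from hypermutated samples
#'
#' A sample is hypermutated when its total mutation count across the whole
#' cohort (not per gene) exceeds `max_per_sample`; all of its mutations
#' are removed.  A sample with exactly `max_per_sample` mutations is kept.
#'
#' @param mutations mutation data.table
#' @param max_per_sample strict upper bound on per-sample mutation burden
#'   (default 100)
#' @return list(`mutations`, `report`)
#' @export
filter_hypermutated <- function(mutations, max_per_sample = 100L) {
  mutations <- data.table::as.data.table(mutations)
  if (nrow(mutations) == 0L) {
    return(list(mutations = mutations,
                report = filter_report("hypermutated", 0L,
                                       list(max_per_sample = max_per_sample))))
  }
  burden <- mutations[, .N, by = sample_id]
  hyper <- burden[N > max_per_sample, sample_id]
  keep <- !(mutations$sample_id %in% hyper)
  list(mutations = mutations[keep],
       report = filter_report("hypermutated", sum(!keep),
                              list(max_per_sample = max_per_sample),
                              removed_samples = sort(hyper)))
}

#' Discard point mutations at common SNP positions
#'
#' Only missense (point) mutations coinciding with a listed SNP position
#' are removed; insertions and deletions are untouched even when their
#' span covers a listed position.
#'
#' @param mutations mutation data.table
#' @param snp_positions data.table with `isoform_id`, `position` (see
#'   [read_exclusions()])
#' @return list(`mutations`, `report`)
#' @export
filter_snp_positions <- function(mutations, snp_positions) {
  mutations <- data.table::as.data.table(mutations)
  snp_positions <- data.table::as.data.table(snp_positions)
  if (nrow(mutations) == 0L || nrow(snp_positions) == 0L) {
    return(list(mutations = mutations,
                report = filter_report("snp_positions", 0L,
                                       list(n_snp_positions = nrow(snp_positions)))))
  }
  key <- paste(mutations$isoform_id, mutations$start)
  snp_key <- unique(paste(snp_positions$isoform_id, snp_positions$position))
  remove <- mutations$mtype == "missense" & key %in% snp_key
  list(mutations = mutations[!remove],
       report = filter_report("snp_positions", sum(remove),
                              list(n_snp_positions = length(snp_key))))
}

# Pairwise sharing between two samples' variation-key sets, relative to the
# smaller set.
share_fraction <- function(keys_a, keys_b) {
  length(intersect(keys_a, keys_b)) / min(length(keys_a), length(keys_b))
}

#' Collapse clonal (near-duplicate) samples
#'
#' Samples with at least `min_mutations` mutations that share at least
#' `min_shared_fraction` of their local variations are treated as clonal
#' duplicates.  A variation is "shared" when identical in
#' (isoform, start, end, type, alternate residue); the sharing fraction is
#' computed relative to the smaller sample's distinct-variation count, and
#' qualifying pairs are grouped by transitive closure.  Within each group
#' only the most mutation-rich sample is retained (ties break to the
#' lexicographically smallest sample ID).
#'
#' @param mutations mutation data.table
#' @param min_mutations minimum per-sample mutation count to participate
#'   (default 5)
#' @param min_shared_fraction minimum shared fraction (default 0.5)
#' @return list(`mutations`, `report`)
#' @export
filter_clonal_samples <- function(mutations, min_mutations = 5L,
                                  min_shared_fraction = 0.5) {
  mutations <- data.table::as.data.table(mutations)
  params <- list(min_mutations = min_mutations,
                 min_shared_fraction = min_shared_fraction)
  if (nrow(mutations) == 0L) {
    return(list(mutations = mutations,
                report = filter_report("clonal_samples", 0L, params)))
  }
  mutations[, .variation_key := paste(isoform_id, start, end, mtype, alt_aa,
                                      sep = "\r")]
  burden <- mutations[, .(n_mut = .N), by = sample_id]
  eligible <- burden[n_mut >= min_mutations, sample_id]
  removed_samples <- character(0)
  if (length(eligible) >= 2L) {
    keysets <- lapply(
      setNames(eligible, eligible),
      function(s) unique(mutations[sample_id == s, .variation_key])
    )
    ns <- length(eligible)
    # union-find over qualifying pairs (transitive grouping)
    parent <- seq_len(ns)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(ns - 1L)) {
      for (j in seq.int(i + 1L, ns)) {
        if (share_fraction(keysets[[i]], keysets[[j]]) >= min_shared_fraction) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    comp <- vapply(seq_len(ns), find, integer(1))
    burden_map <- setNames(burden$n_mut, burden$sample_id)
    for (cc in unique(comp)) {
      members <- eligible[comp == cc]
      if (length(members) < 2L) next
      ord <- order(-burden_map[members], members)
      removed_samples <- c(removed_samples, members[ord][-1L])
    }
  }
  keep <- !(mutations$sample_id %in% removed_samples)
  out <- mutations[keep]
  out[, .variation_key := NULL]
  mutations[, .variation_key := NULL]
  list(mutations = out,
       report = filter_report("clonal_samples", sum(!keep), params,
                              removed_samples = sort(removed_samples)))
}

#' Discard mutations overlapping low-complexity intervals
#'
#' A mutation is removed when its closed span `[start, end]` intersects
#' any listed low-complexity interval on its isoform.
#'
#' @param mutations mutation data.table
#' @param low_complexity data.table with `isoform_id`, `start`, `end`
#' @return list(`mutations`, `report`)
#' @export
filter_low_complexity <- function(mutations, low_complexity) {
  mutations <- data.table::as.data.table(mutations)
  low_complexity <- data.table::as.data.table(low_complexity)
  if (nrow(mutations) == 0L || nrow(low_complexity) == 0L) {
    return(list(mutations = mutations,
                report = filter_report("low_complexity", 0L,
                                       list(n_intervals = nrow(low_complexity)))))
  }
  remove <- protein_overlaps_any(
    mutations$isoform_id, mutations$start, mutations$end,
    low_complexity$isoform_id, low_complexity$start, low_complexity$end
  )
  list(mutations = mutations[!remove],
       report = filter_report("low_complexity", sum(remove),
                              list(n_intervals = nrow(low_complexity))))
}

#' Run all cleaning filters in the fixed order
#'
#' Applies hypermutated -> SNP -> clonal -> low-complexity.  The order is
#' fixed because SNP-vs-clonal ordering can change results on adversarial
#' inputs; the composition's output is invariant to input row order.
#'
#' @param mutations raw validated mutation data.table
#' @param exclusions list from [read_exclusions()] (may be NULL)
#' @param max_per_sample,min_mutations,min_shared_fraction filter
#'   thresholds, see the individual filters
#' @return list(`mutations` cleaned rows, `reports` list of one report per
#'   filter, `removed` data.table of removed rows with a `filter_reason`
#'   column)
#' @export
clean_mutations <- function(mutations, exclusions = NULL,
                            max_per_sample = 100L, min_mutations = 5L,
                            min_shared_fraction = 0.5) {
  mutations <- data.table::as.data.table(mutations)
  if (is.null(exclusions)) {
    exclusions <- list(
      snp_positions = data.table::data.table(isoform_id = character(0),
                                             position = integer(0)),
      low_complexity = data.table::data.table(isoform_id = character(0),
                                              start = integer(0),
                                              end = integer(0))
    )
  }
  removed <- list()
  grab_removed <- function(before, after, name) {
    gone <- before[!after, on = names(before)]
    if (nrow(gone)) gone[, filter_reason := name]
    gone
  }
  s1 <- filter_hypermutated(mutations, max_per_sample)
  removed$hyper <- grab_removed(mutations, s1$mutations, "hypermutated")
  s2 <- filter_snp_positions(s1$mutations, exclusions$snp_positions)
  removed$snp <- grab_removed(s1$mutations, s2$mutations, "snp_position")
  s3 <- filter_clonal_samples(s2$mutations, min_mutations, min_shared_fraction)
  removed$clonal <- grab_removed(s2$mutations, s3$mutations, "clonal_sample")
  s4 <- filter_low_complexity(s3$mutations, exclusions$low_complexity)
  removed$lc <- grab_removed(s3$mutations, s4$mutations, "low_complexity")
  list(mutations = s4$mutations,
       reports = list(hypermutated = s1$report,
                      snp_positions = s2$report,
                      clonal_samples = s3$report,
                      low_complexity = s4$report),
       removed = data.table::rbindlist(removed, fill = TRUE))
}
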