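#' Scan configuration for the region caller
#'
#' @param seed_lengths seed window lengths in residues scanned over each
#'   protein (default 7, 10 and 30, spanning short motifs to domain-sized
#'   segments)
#' @param alpha raw p-value gate for seeds (default 0.01; no
#'   multiple-testing correction is applied across windows or genes, which
#'   is deliberate and should be kept in mind when interpreting
#'   low-significance calls)
#' @param tier_bounds two descending p-value cutpoints separating the
#'   high / medium / low significance tiers (default 1e-20, 1e-5)
#' @param merge_overlapping merge overlapping optimized intervals
#'   (default TRUE)
#' @param min_fraction minimum fraction of a region's mutations a cancer
#'   type must contribute to be listed as associated (default 0.2)
#' @return object of class `scan_config`
#' @export
scan_config <- function(seed_lengths = c(7L, 10L, 30L), alpha = 0.01,
                        tier_bounds = c(1e-20, 1e-5),
                        merge_overlapping = TRUE, min_fraction = 0.2) {
  seed_lengths <- sort(unique(as.integer(seed_lengths)))
  stopifnot(all(seed_lengths >= 1L), alpha > 0, alpha < 1,
            length(tier_bounds) == 2L, tier_bounds[1] < tier_bounds[2],
            min_fraction >= 0, min_fraction <= 1)
  structure(list(seed_lengths = seed_lengths, alpha = alpha,
                 tier_bounds = as.numeric(tier_bounds),
                 merge_overlapping = isTRUE(merge_overlapping),
                 min_fraction = min_fraction),
            class = "scan_config")
}

#' Count mutation events inside and outside an interval
#'
#' An event counts as inside when its closed span `[start, end]`
#' intersects the interval; each event counts exactly once (deletions
#' straddling a boundary are inside, never split).
#'
#' @param gene a [gene_mutation_set()]
#' @param start,end interval bounds, 1-based inclusive, within
#'   `[1, gene$length]`
#' @param restrict_type optionally count only one of
#'   `"missense"`, `"insertion"`, `"deletion"`
#' @return named integer vector `c(m_in, m_out)`
#' @export
count_events <- function(gene, start, end, restrict_type = NULL) {
  if (start < 1L || end > gene$length || start > end) {
    stop("interval out of bounds for ", gene$gene_id)
  }
  mut <- gene$mutations
  if (!is.null(restrict_type)) mut <- mut[mtype == restrict_type]
  if (nrow(mut) == 0L) return(c(m_in = 0L, m_out = 0L))
  inside <- mut$start <= end & mut$end >= start
  c(m_in = sum(inside), m_out = sum(!inside))
}

#' Enumerate seed windows and keep the significantly enriched ones
#'
#' Every window of each configured seed length is tested for mutation
#' enrichment with [region_pvalue()]; when the protein is shorter than a
#' seed length the window degenerates to the full protein so short
#' proteins remain scannable.  Windows with `p < alpha` are returned.
#'
#' @param gene a [gene_mutation_set()]
#' @param config a [scan_config()]
#' @return data.table with `start`, `end`, `seed_length`, `p`
#' @export
scan_seeds <- function(gene, config = scan_config()) {
  L <- gene$length
  mut <- gene$mutations
  empty <- data.table::data.table(start = integer(0), end = integer(0),
                                  seed_length = integer(0), p = numeric(0))
  if (nrow(mut) == 0L) return(empty)
  ev <- IRanges::IRanges(mut$start, mut$end)
  M <- nrow(mut)
  out <- lapply(config$seed_lengths, function(k) {
    starts <- seq_len(max(1L, L - k + 1L))
    ends <- pmin(L, starts + k - 1L)
    win <- IRanges::IRanges(starts, ends)
    m_in <- IRanges::countOverlaps(win, ev)
    len_in <- ends - starts + 1L
    p <- region_pvalue(m_in, M - m_in, len_in, L - len_in)
    data.table::data.table(start = starts, end = ends,
                           seed_length = k, p = p)[p < config$alpha]
  })
  data.table::rbindlist(c(list(empty), out))
}

# p-value of [s, e] given precomputed event spans; Inf-guarded caller must
# ensure 1 <= s <= e <= L.
interval_pvalue <- function(s, e, ev_start, ev_end, L) {
  m_in <- sum(ev_start <= e & ev_end >= s)
  len_in <- e - s + 1L
  region_pvalue(m_in, length(ev_start) - m_in, len_in, L - len_in)
}

#' Greedy boundary optimization of a significant seed window
#'
#' Hill-climbs from a seed interval: at each step the four single-residue
#' boundary moves (extend/shrink on either side) are evaluated and the one
#' with the lowest p-value is applied if strictly lower than the current
#' p; the climb stops at a local optimum.  Ties between improving moves
#' break to the shorter resulting interval, then to the leftward one, so
#' the result is deterministic.  The interval never shrinks below one
#' residue and never leaves `[1, length]`.
#'
#' @param start,end seed interval (must have passed the alpha gate)
#' @param gene a [gene_mutation_set()]
#' @return list(`start`, `end`, `p`)
#' @export
optimize_boundaries <- function(start, end, gene) {
  L <- gene$length
  ev_start <- gene$mutations$start
  ev_end <- gene$mutations$end
  M <- length(ev_start)
  s <- as.integer(start); e <- as.integer(end)
  p <- interval_pvalue(s, e, ev_start, ev_end, L)
  repeat {
    cs <- c(s - 1L, s + 1L, s, s)
    ce <- c(e, e, e + 1L, e - 1L)
    ok <- cs >= 1L & ce <= L & cs <= ce
    cs <- cs[ok]; ce <- ce[ok]
    if (!length(cs)) break
    m_in <- vapply(seq_along(cs), function(i) {
      sum(ev_start <= ce[i] & ev_end >= cs[i])
    }, numeric(1))
    len_in <- ce - cs + 1L
    pc <- region_pvalue(m_in, M - m_in, len_in, L - len_in)
    best <- order(pc, len_in, cs, ce)[1L]
    if (pc[best] >= p) break
    s <- cs[best]; e <- ce[best]; p <- pc[best]
  }
  list(start = s, end = e, p = p)
}

#' Merge overlapping optimized intervals
#'
#' Overlapping closed intervals are unioned transitively and the
#' enrichment p-value is recomputed once on each merged span.  Merged
#' regions are retained even when the recomputed p exceeds the gate
#' (each constituent was individually significant); such regions carry
#' `above_alpha = TRUE` so downstream consumers can see the flag.
#'
#' @param intervals data.table with `start`, `end` (optimized intervals of
#'   one gene)
#' @param gene a [gene_mutation_set()]
#' @param config a [scan_config()]
#' @return data.table with `start`, `end`, `p`, `above_alpha`
#' @export
merge_regions <- function(intervals, gene, config = scan_config()) {
  empty <- data.table::data.table(start = integer(0), end = integer(0),
                                  p = numeric(0), above_alpha = logical(0))
  if (nrow(intervals) == 0L) return(empty)
  iv <- unique(intervals[, .(start, end)])
  ir <- IRanges::IRanges(iv$start, iv$end)
  merged <- if (config$merge_overlapping) IRanges::reduce(ir) else ir
  ev_start <- gene$mutations$start
  ev_end <- gene$mutations$end
  out <- data.table::data.table(start = IRanges::start(merged),
                                end = IRanges::end(merged))
  out[, p := vapply(seq_len(.N), function(i) {
    interval_pvalue(start[i], end[i], ev_start, ev_end, gene$length)
  }, numeric(1))]
  out[, above_alpha := p >= config$alpha]
  data.table::setorder(out, start)
  out[]
}

#' Assign a significance tier to a region p-value
#'
#' Tiers: high for `p <= tier_bounds[1]`, medium for
#' `p <= tier_bounds[2]`, low otherwise.  A p-value exactly on a bound is
#' assigned to the more significant tier.
#'
#' @param p region p-value(s), each `<= alpha` (a larger value means the
#'   interval should never have been called and is an error)
#' @param tier_bounds ascending cutpoints, default `c(1e-20, 1e-5)`
#' @param alpha the calling gate (default 0.01)
#' @return character vector of `"high"`, `"medium"`, `"low"`
#' @export
classify_significance <- function(p, tier_bounds = c(1e-20, 1e-5),
                                  alpha = 0.01) {
  if (any(p > alpha)) stop("p-value above the calling gate has no tier")
  ifelse(p <= tier_bounds[1], "high",
         ifelse(p <= tier_bounds[2], "medium", "low"))
}

#' Per-type p-values and dominant mutation type of a region
#'
#' The region p-value is recomputed restricted to each mutation class in
#' turn (both the inside and outside counts restricted to that class);
#' the class with the lowest restricted p-value is the dominant one.
#' Ties break by the fixed priority missense > deletion > insertion.
#'
#' @param start,end region interval
#' @param gene a [gene_mutation_set()]
#' @return list(`dominant_type`, `p_by_type` named numeric over the three
#'   classes)
#' @export
dominant_mutation_type <- function(start, end, gene) {
  priority <- c("missense", "deletion", "insertion")
  p_by_type <- vapply(priority, function(tp) {
    cnt <- count_events(gene, start, end, restrict_type = tp)
    len_in <- end - start + 1L
    region_pvalue(cnt[["m_in"]], cnt[["m_out"]], len_in, gene$length - len_in)
  }, numeric(1))
  dominant <- priority[which.min(p_by_type)]  # which.min takes the first tie
  list(dominant_type = dominant,
       p_by_type = p_by_type[MUTATION_TYPES])
}

#' Cancer-type tally and association for a region
#'
#' Tallies the cancer-type labels of all mutations intersecting the
#' region (unlabeled mutations count as `"unknown"`); types contributing
#' at least `min_fraction` of the region's mutations are reported as
#' associated.
#'
#' @param start,end region interval
#' @param gene a [gene_mutation_set()]
#' @param min_fraction association threshold on the tally fraction
#'   (default 0.2)
#' @return list(`tally` named integer, `associated` character vector)
#' @export
assign_cancer_types <- function(start, end, gene, min_fraction = 0.2) {
  m <- gene$mutations
  sel <- m$start <= end & m$end >= start
  mut <- m[sel]
  labels <- mut$cancer_type
  labels[is.na(labels) | !nzchar(labels)] <- "unknown"
  tally <- sort(table(labels), decreasing = TRUE)
  tally <- setNames(as.integer(tally), names(tally))
  associated <- names(tally)[tally / sum(tally) >= min_fraction]
  list(tally = tally, associated = associated)
}

format_tally <- function(tally) {
  paste(sprintf("%s:%d", names(tally), tally), collapse = ";")
}

#' Call significantly mutated regions in one gene
#'
#' The full per-gene pipeline: seed scan, boundary optimization of every
#' significant seed, merging of overlapping optimized intervals, then
#' tier, per-type p-value, dominant-type and cancer-type annotation of
#' each final region.  The output is sorted by start and deterministic
#' under permutation of the input mutations.
#'
#' @param gene a [gene_mutation_set()]
#' @param config a [scan_config()]
#' @return data.table with one row per region: `gene_id`, `isoform_id`,
#'   `start`, `end`, `length`, `p_total`, `tier`, `above_alpha`,
#'   `dominant_type`, `p_missense`, `p_insertion`, `p_deletion`,
#'   `n_mutations`, `cancer_types` (tally string `label:count;...`),
#'   `associated_cancer_types` (semicolon list)
#' @export
call_regions <- function(gene, config = scan_config()) {
  seeds <- scan_seeds(gene, config)
  empty <- data.table::data.table(
    gene_id = character(0), isoform_id = character(0), start = integer(0),
    end = integer(0), length = integer(0), p_total = numeric(0),
    tier = character(0), above_alpha = logical(0),
    dominant_type = character(0), p_missense = numeric(0),
    p_insertion = numeric(0), p_deletion = numeric(0),
    n_mutations = integer(0), cancer_types = character(0),
    associated_cancer_types = character(0)
  )
  if (nrow(seeds) == 0L) return(empty)
  opt_se <- vapply(seq_len(nrow(seeds)), function(i) {
    o <- optimize_boundaries(seeds$start[i], seeds$end[i], gene)
    c(o$start, o$end)
  }, integer(2))
  opt <- unique(data.table::data.table(start = opt_se[1, ], end = opt_se[2, ]))
  merged <- merge_regions(opt, gene, config)
  if (nrow(merged) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(merged)), function(i) {
    s <- merged$start[i]; e <- merged$end[i]; p <- merged$p[i]
    dom <- dominant_mutation_type(s, e, gene)
    ct <- assign_cancer_types(s, e, gene, config$min_fraction)
    cnt <- count_events(gene, s, e)
    tier <- if (p <= config$alpha) {
      classify_significance(p, config$tier_bounds, config$alpha)
    } else NA_character_
    data.table::data.table(
      gene_id = gene$gene_id, isoform_id = gene$isoform_id,
      start = s, end = e, length = e - s + 1L, p_total = p, tier = tier,
      above_alpha = merged$above_alpha[i],
      dominant_type = dom$dominant_type,
      p_missense = dom$p_by_type[["missense"]],
      p_insertion = dom$p_by_type[["insertion"]],
      p_deletion = dom$p_by_type[["deletion"]],
      n_mutations = cnt[["m_in"]],
      cancer_types = format_tally(ct$tally),
      associated_cancer_types = paste(ct$associated, collapse = ";")
    )
  })
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, start)
  out[]
}

#' Call regions across a whole cohort
#'
#' @param gene_sets named list from [build_gene_sets()]
#' @param config a [scan_config()]
#' @return data.table of all called regions, ordered by gene then start
#' @export
call_regions_cohort <- function(gene_sets, config = scan_config()) {
  out <- data.table::rbindlist(lapply(gene_sets, call_regions, config = config))
  if (nrow(out)) data.table::setorder(out, gene_id, start)
  out[]
}
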