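# GRanges keyed by protein ID with a shared seqlevel universe, so overlap
# queries between tables covering different protein subsets stay silent.
protein_granges <- function(ids, start, end, levels) {
  GenomicRanges::GRanges(factor(ids, levels = levels),
                         IRanges::IRanges(start, end))
}

# overlapsAny across two (id, start, end) tables
protein_overlaps_any <- function(q_ids, q_start, q_end,
                                 s_ids, s_start, s_end) {
  levels <- sort(unique(c(q_ids, s_ids)))
  IRanges::overlapsAny(
    protein_granges(q_ids, q_start, q_end, levels),
    protein_granges(s_ids, s_start, s_end, levels)
  )
}
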