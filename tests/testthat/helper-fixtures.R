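# Compact builders for mutation fixtures used across the suite.

mut_row <- function(gene = "G1", iso = paste0(gene, ".1"), sample = "S1",
                    start = 1L, end = start, mtype = "missense",
                    ref = "R", alt = "H", cancer = "Melanoma") {
  data.table::data.table(gene_id = gene, isoform_id = iso, sample_id = sample,
                         start = as.integer(start), end = as.integer(end),
                         mtype = mtype, ref_aa = ref, alt_aa = alt,
                         cancer_type = cancer)
}

# n missense mutations at given positions, one sample each
mut_at <- function(positions, gene = "G1", sample_prefix = "S",
                   cancer = "Melanoma") {
  if (length(positions) == 0L) return(mut_row()[0])
  data.table::rbindlist(lapply(seq_along(positions), function(i) {
    mut_row(gene = gene, sample = sprintf("%s%04d", sample_prefix, i),
            start = positions[i], cancer = cancer)
  }))
}

make_gene <- function(mutations, length = 500L, gene = "G1",
                      iso = paste0(gene, ".1")) {
  gene_mutation_set(gene, iso, length, mutations)
}

write_tsv_fixture <- function(dt, dir = tempdir(), name = "fixture.tsv") {
  path <- file.path(dir, name)
  data.table::fwrite(dt, path, sep = "\t")
  path
}

write_fasta_fixture <- function(seqs, dir = tempdir(), name = "fixture.fasta") {
  path <- file.path(dir, name)
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             path)
  path
}
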