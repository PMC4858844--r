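test_that("event counting uses closed-span intersection, once per event", {
  muts <- rbind(
    mut_row(sample = "S1", start = 5, end = 9, mtype = "deletion", ref = "A", alt = ""),
    mut_row(sample = "S2", start = 30),
    mut_row(sample = "S3", start = 8, mtype = "insertion", ref = "", alt = "Q")
  )
  g <- make_gene(muts, length = 100L)
  expect_equal(count_events(g, 8, 20), c(m_in = 2L, m_out = 1L))
  expect_equal(count_events(g, 8, 20, restrict_type = "missense"),
               c(m_in = 0L, m_out = 1L))
  expect_equal(count_events(g, 8, 20, restrict_type = "deletion"),
               c(m_in = 1L, m_out = 0L))
  expect_error(count_events(g, 0, 10), "out of bounds")
  expect_error(count_events(g, 90, 101), "out of bounds")
  empty <- make_gene(mut_at(integer(0)), length = 100L)
  expect_equal(count_events(empty, 1, 100), c(m_in = 0L, m_out = 0L))
})

test_that("seed scan enumerates L-k+1 windows per seed length", {
  # with a mutation at every position and a near-1 gate, every window is
  # returned, exposing the enumeration arithmetic
  g <- make_gene(mut_at(1:100), length = 100L)
  cfg <- scan_config(seed_lengths = c(7, 10, 30), alpha = 0.9999)
  seeds <- scan_seeds(g, cfg)
  expect_equal(sum(seeds$seed_length == 7), 94L)
  expect_equal(sum(seeds$seed_length == 10), 91L)
  expect_equal(sum(seeds$seed_length == 30), 71L)
})

test_that("short proteins degenerate to a single clipped full-length window", {
  g <- make_gene(mut_at(c(3, 3, 3), gene = "G1"), length = 20L)
  cfg <- scan_config(seed_lengths = 30, alpha = 0.9999)
  seeds <- scan_seeds(g, cfg)
  # the only window covers the whole protein: len_out = 0, p = 1, never kept
  expect_equal(nrow(seeds), 0L)
})

test_that("uniform sparse genes yield no significant seeds", {
  g <- make_gene(mut_at(seq(50, 500, by = 50)), length = 500L)
  expect_equal(nrow(scan_seeds(g)), 0L)
  expect_equal(nrow(call_regions(g)), 0L)
})

test_that("a stacked hotspot yields a significant seed containing it", {
  g <- make_gene(mut_at(rep(50, 20)), length = 500L)
  seeds <- scan_seeds(g)
  expect_gt(nrow(seeds), 0L)
  expect_true(any(seeds$start <= 50 & seeds$end >= 50))
  expect_true(all(seeds$p < 0.01))
})

test_that("boundary optimization tightens onto the hotspot and never widens p", {
  muts <- mut_at(c(rep(50, 8), rep(51, 6), rep(52, 6), 200, 300, 400))
  g <- make_gene(muts, length = 500L)
  seed_p <- interval_p <- region_pvalue(20, 3, 7, 493)
  opt <- optimize_boundaries(48, 54, g)
  expect_lte(opt$p, seed_p)
  expect_equal(c(opt$start, opt$end), c(50L, 52L))
})

test_that("optimization absorbs an adjacent stack outside the seed", {
  muts <- mut_at(c(rep(50, 10), rep(55, 5), rep(56, 5), rep(57, 5)))
  g <- make_gene(muts, length = 500L)
  opt <- optimize_boundaries(48, 54, g)
  expect_gte(opt$end, 57L)
})

test_that("an exactly-filling hotspot is a local optimum", {
  muts <- mut_at(c(rep(48, 5), rep(50, 5), rep(52, 5), rep(54, 5)))
  g <- make_gene(muts, length = 500L)
  opt <- optimize_boundaries(48, 54, g)
  expect_equal(c(opt$start, opt$end), c(48L, 54L))
})

test_that("merging unions overlapping intervals transitively", {
  g <- make_gene(mut_at(rep(c(12, 20, 28), each = 5)), length = 500L)
  iv <- data.table::data.table(start = c(10L, 18L, 25L), end = c(20L, 30L, 40L))
  merged <- merge_regions(iv, g)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(10L, 40L))
  iv2 <- data.table::data.table(start = c(10L, 25L), end = c(20L, 30L))
  merged2 <- merge_regions(iv2, g)
  expect_equal(nrow(merged2), 2L)
})

test_that("significance tiers follow the thresholds, boundaries upward", {
  expect_equal(classify_significance(1.050e-14), "medium")
  expect_equal(classify_significance(1e-25), "high")
  expect_equal(classify_significance(9.9e-3), "low")
  expect_equal(classify_significance(1e-20), "high")
  expect_equal(classify_significance(1e-5), "medium")
  expect_error(classify_significance(0.02), "gate")
})

test_that("dominant type is the argmin of restricted p-values", {
  only_mis <- make_gene(mut_at(rep(50, 10)), length = 500L)
  expect_equal(dominant_mutation_type(45, 55, only_mis)$dominant_type, "missense")

  dels <- data.table::rbindlist(lapply(1:10, function(i) {
    mut_row(sample = sprintf("D%d", i), start = 50, end = 52,
            mtype = "deletion", ref = "A", alt = "")
  }))
  mixed <- make_gene(rbind(dels, mut_at(50)), length = 500L)
  dom <- dominant_mutation_type(45, 55, mixed)
  expect_equal(dom$dominant_type, "deletion")
  expect_lt(dom$p_by_type[["deletion"]], dom$p_by_type[["missense"]])

  # exact tie between classes resolves by fixed priority
  ins <- data.table::copy(dels)[, `:=`(mtype = "insertion", end = start,
                                       ref_aa = "", alt_aa = "Q")]
  tie <- make_gene(rbind(dels[, .SD, .SDcols = names(dels)][, end := start],
                         ins), length = 500L)
  expect_equal(dominant_mutation_type(45, 55, tie)$dominant_type, "deletion")
})

test_that("cancer-type association applies the tally-fraction threshold", {
  lab <- function(n, type) mut_at(rep(50, n), cancer = type)
  g1 <- make_gene(lab(10, "Acute myeloid leukemia"), length = 200L)
  expect_equal(assign_cancer_types(40, 60, g1)$associated,
               "Acute myeloid leukemia")
  g2 <- make_gene(rbind(lab(6, "GIST"), lab(4, "Acute myeloid leukemia")),
                  length = 200L)
  expect_setequal(assign_cancer_types(40, 60, g2)$associated,
                  c("GIST", "Acute myeloid leukemia"))
  g3 <- make_gene(rbind(lab(9, "Melanoma"), lab(1, "Lymphoma")), length = 200L)
  expect_equal(assign_cancer_types(40, 60, g3)$associated, "Melanoma")
  # unlabeled mutations tally under "unknown"
  g4 <- make_gene(mut_at(rep(50, 4), cancer = ""), length = 200L)
  expect_equal(names(assign_cancer_types(40, 60, g4)$tally), "unknown")
})

test_that("call_regions recovers a planted stack and is order-invariant", {
  set.seed(9)
  muts <- rbind(mut_at(rep(100, 15)), mut_at(sample.int(800, 8), sample_prefix = "B"))
  g <- make_gene(muts, length = 800L)
  regs <- call_regions(g)
  expect_equal(nrow(regs), 1L)
  expect_true(regs$start <= 100 & regs$end >= 100)
  expect_equal(regs$tier, "high")
  expect_equal(regs$dominant_type, "missense")
  # invariance to mutation row order
  g2 <- make_gene(muts[sample(.N)], length = 800L)
  expect_equal(call_regions(g2), regs)
  # zero mutations
  expect_equal(nrow(call_regions(make_gene(mut_at(integer(0)), length = 800L))), 0L)
})

test_that("region p-values and mutation counts are internally consistent", {
  set.seed(21)
  muts <- rbind(mut_at(rep(60, 12)), mut_at(rep(200, 9), sample_prefix = "C"),
                mut_at(sample.int(900, 10), sample_prefix = "B"))
  g <- make_gene(muts, length = 900L)
  regs <- call_regions(g)
  expect_gte(nrow(regs), 2L)
  for (i in seq_len(nrow(regs))) {
    cnt <- count_events(g, regs$start[i], regs$end[i])
    expect_equal(regs$n_mutations[i], unname(cnt["m_in"]))
    len_in <- regs$end[i] - regs$start[i] + 1L
    expect_equal(regs$p_total[i],
                 region_pvalue(cnt["m_in"], cnt["m_out"], len_in, 900 - len_in))
    tally <- as.integer(sub(".*:", "", strsplit(regs$cancer_types[i], ";")[[1]]))
    expect_equal(sum(tally), regs$n_mutations[i])
  }
})
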