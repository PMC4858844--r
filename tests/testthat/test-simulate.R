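test_that("a null spec with zero rate yields an empty cohort", {
  spec <- sim_spec(n_genes = 3, length_range = c(200, 300),
                   background_rate = 0, rng_seed = 4)
  co <- simulate_cohort(spec)
  expect_equal(nrow(co$mutations), 0L)
  expect_equal(length(co$sequences), 3L)
  expect_equal(nrow(co$truth), 0L)
})

test_that("simulation is byte-identical under a fixed seed", {
  spec <- sim_spec(n_genes = 5, background_rate = 0.02,
                   plants = list(list(gene = 2, start = 50, width = 12, fold = 25)),
                   n_hypermutated = 1, n_clonal_pairs = 1, n_snp_events = 2,
                   n_low_complexity_events = 2, rng_seed = 99)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$exclusions, b$exclusions)
  expect_identical(a$truth, b$truth)
  d1 <- file.path(tempdir(), "cohortA"); d2 <- file.path(tempdir(), "cohortB")
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("adding genes does not perturb earlier genes' draws", {
  s5 <- sim_spec(n_genes = 5, background_rate = 0.02, rng_seed = 12)
  s8 <- sim_spec(n_genes = 8, background_rate = 0.02, rng_seed = 12)
  a <- simulate_cohort(s5); b <- simulate_cohort(s8)
  expect_identical(a$sequences, b$sequences[1:5])
  expect_identical(a$mutations, b$mutations[gene_id <= "GENE0005"])
})

test_that("confounders trigger their filters exactly as constructed", {
  spec <- sim_spec(n_genes = 4, length_range = c(500, 800),
                   background_rate = 0.005,
                   n_hypermutated = 1, hypermutated_burden = 150,
                   n_clonal_pairs = 1, n_snp_events = 3,
                   n_low_complexity_events = 4, rng_seed = 7)
  co <- simulate_cohort(spec)
  cleaned <- clean_mutations(co$mutations, co$exclusions)
  expect_equal(cleaned$reports$hypermutated$removed_count, 150L)
  expect_equal(cleaned$reports$hypermutated$removed_samples, "HYPER001")
  # one clonal sample of the pair goes (6 mutations each, 5 shared)
  expect_equal(cleaned$reports$clonal_samples$removed_count, 6L)
  expect_match(cleaned$reports$clonal_samples$removed_samples, "^CLONE001")
  expect_equal(cleaned$reports$snp_positions$removed_count, 3L)
  expect_equal(cleaned$reports$low_complexity$removed_count, 4L)
})

test_that("planted and background event counts track their Poisson rates", {
  n <- 40
  plants <- lapply(seq_len(n), function(i) list(gene = i, start = 100,
                                                width = 20, fold = 30))
  spec <- sim_spec(n_genes = n, length_range = c(1000, 1000),
                   background_rate = 0.01, plants = plants, rng_seed = 23)
  co <- simulate_cohort(spec)
  # plant counts: lambda = 20 * 0.01 * 30 = 6 per gene
  lam_p <- 20 * 0.01 * 30
  expect_lt(abs(mean(co$truth$n_planted) - lam_p), 4 * sqrt(lam_p / n))
  # background: lambda = 1000 * 0.01 = 10 per gene
  n_bg <- nrow(co$mutations) - sum(co$truth$n_planted)
  lam_b <- 1000 * 0.01
  expect_lt(abs(n_bg / n - lam_b), 4 * sqrt(lam_b / n))
  # planted events stay inside their interval
  planted_mut <- co$mutations[start >= 100 & start <= 119]
  expect_gte(nrow(planted_mut), sum(co$truth$n_planted))
})

test_that("annotation tracks are reproducible and co-localize when asked", {
  lengths <- setNames(rep(300L, 10), sprintf("P%02d", 1:10))
  t1 <- simulate_annotation_tracks(lengths, rng_seed = 3)
  t2 <- simulate_annotation_tracks(lengths, rng_seed = 3)
  expect_identical(t1, t2)
  expect_equal(nrow(t1$disorder), 3000L)
  expect_true(all(t1$disorder$score >= 0 & t1$disorder$score <= 1))
  expect_setequal(unique(t1$tracks$category) %in% c("domain", "motif", "site"),
                  TRUE)
  regions <- data.table::data.table(protein_id = names(lengths),
                                    start = 100L, end = 130L)
  te <- simulate_annotation_tracks(lengths, regions = regions, effect = 50,
                                   rng_seed = 3)
  reg_gr <- GenomicRanges::GRanges(regions$protein_id,
                                   IRanges::IRanges(regions$start, regions$end))
  trk_gr <- GenomicRanges::GRanges(te$tracks$protein_id,
                                   IRanges::IRanges(te$tracks$start, te$tracks$end))
  base_gr <- GenomicRanges::GRanges(t1$tracks$protein_id,
                                    IRanges::IRanges(t1$tracks$start, t1$tracks$end))
  expect_gt(sum(IRanges::overlapsAny(reg_gr, trk_gr)),
            sum(IRanges::overlapsAny(reg_gr, base_gr)))
  empty <- simulate_annotation_tracks(setNames(integer(0), character(0)))
  expect_equal(nrow(empty$tracks), 0L)
})

test_that("infeasible plants are rejected", {
  spec <- sim_spec(n_genes = 1, length_range = c(100, 100),
                   plants = list(list(gene = 1, start = 95, width = 10, fold = 5)),
                   rng_seed = 1)
  expect_error(simulate_cohort(spec), "bounds")
})
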