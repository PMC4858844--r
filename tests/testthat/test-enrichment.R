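test_that("disorder smoothing matches a brute-force moving average", {
  set.seed(13)
  raw <- stats::runif(200)
  calls <- smooth_disorder(raw, window = 31, threshold = 0.5)
  brute <- vapply(seq_along(raw), function(i) {
    mean(raw[max(1, i - 15):min(200, i + 15)]) > 0.5
  }, logical(1))
  expect_equal(calls, brute)
  expect_error(smooth_disorder(raw, window = 30), "odd")
})

test_that("domain intervals override disorder calls; binding scores add them", {
  raw <- rep(0.8, 100)
  calls <- smooth_disorder(raw)
  expect_true(all(calls))
  dom <- data.frame(start = 10, end = 40)
  calls2 <- smooth_disorder(raw, domain_intervals = dom)
  expect_false(any(calls2[10:40]))
  expect_true(all(calls2[c(1:9, 41:100)]))
  # an ordered backbone with a high binding-score segment is still called
  raw0 <- rep(0.1, 100)
  bind <- c(rep(0, 50), rep(0.9, 10), rep(0, 40))
  calls3 <- smooth_disorder(raw0, binding = bind)
  expect_true(all(calls3[51:60]))
  expect_false(any(calls3[c(1:50, 61:100)]))
})

test_that("disorder content is the fraction of disordered residues", {
  expect_equal(disorder_content(rep(FALSE, 40)), 0)
  expect_equal(disorder_content(rep(c(TRUE, FALSE), 20)), 0.5)
  expect_equal(disorder_content(c(rep(TRUE, 31), rep(FALSE, 93))), 0.25)
  expect_equal(disorder_content(logical(0)), 0)
})

test_that("placements are reproducible, matched, and uniform over starts", {
  proteome <- data.table::data.table(
    protein_id = c("P1", "P2", "P3"),
    length = c(100L, 102L, 300L),
    disorder_content = c(0.30, 0.31, 0.30)
  )
  regions <- data.table::data.table(protein_id = "P1", start = 40L, end = 49L)
  a <- randomize_placements(regions, proteome, n = 500, rng_seed = 7)
  b <- randomize_placements(regions, proteome, n = 500, rng_seed = 7)
  expect_identical(a, b)
  # P3 is 3x longer: never an eligible target at 10% tolerance
  expect_setequal(unique(a$placements$protein_id), c("P1", "P2"))
  expect_true(all(a$placements$end - a$placements$start + 1L == 10L))
  expect_true(all(a$placements$start >= 1L))
  expect_true(all(a$placements$end <= 102L))

  # single self-matching protein: starts uniform over valid positions
  solo <- proteome[1]
  n <- 10000
  pl <- randomize_placements(regions, solo, n = n, rng_seed = 11)$placements
  tab <- tabulate(pl$start, nbins = 91)
  gof <- stats::chisq.test(tab, p = rep(1 / 91, 91))
  expect_gt(gof$p.value, 0.001)
})

test_that("regions with no eligible target are skipped and reported", {
  proteome <- rbind(
    data.table::data.table(protein_id = "P1", length = 50L,
                           disorder_content = 0.2),
    data.table::data.table(protein_id = "P2", length = 45L,
                           disorder_content = 0.2)
  )
  regions <- data.table::data.table(protein_id = "P1", start = 1L, end = 50L)
  res <- randomize_placements(regions, proteome, tolerance = 0.1, n = 10,
                              rng_seed = 1)
  # only P1 itself can host the 50-residue region
  expect_setequal(unique(res$placements$protein_id), "P1")
  # a region wider than every listed protein is skipped outright
  wide <- data.table::data.table(protein_id = "P1", start = 1L, end = 60L)
  res2 <- randomize_placements(wide, proteome, tolerance = 0.1, n = 5,
                               rng_seed = 1)
  expect_equal(nrow(res2$placements), 0L)
  expect_equal(res2$skipped$n_skipped, 5L)
  # a region on a protein missing from the proteome is an input error
  stray <- data.table::data.table(protein_id = "P9", start = 1L, end = 5L)
  expect_error(randomize_placements(stray, proteome, n = 2, rng_seed = 1),
               "absent")
})

test_that("fully ordered proteins match through the absolute fallback band", {
  proteome <- data.table::data.table(
    protein_id = c("P1", "P2"), length = c(100L, 100L),
    disorder_content = c(0.0, 0.04)
  )
  regions <- data.table::data.table(protein_id = "P1", start = 10L, end = 19L)
  pl <- randomize_placements(regions, proteome, n = 200, rng_seed = 3)$placements
  expect_setequal(unique(pl$protein_id), c("P1", "P2"))
})

test_that("z-scores flag planted co-localization and stay null otherwise", {
  set.seed(31)
  n_prot <- 60
  lengths <- setNames(rep(400L, n_prot), sprintf("P%02d", seq_len(n_prot)))
  regions <- data.table::data.table(
    protein_id = names(lengths)[1:20],
    start = 100L, end = 119L
  )
  proteome <- data.table::data.table(protein_id = names(lengths),
                                     length = 400L, disorder_content = 0.3)
  placements <- randomize_placements(regions, proteome, n = 300, rng_seed = 5)

  # planted: the category sits exactly under every region
  planted <- data.table::data.table(protein_id = regions$protein_id,
                                    category = "domain",
                                    start = 100L, end = 119L)
  zres <- enrichment_zscores(regions, placements, planted)
  expect_gte(zres$z, 2.326)
  expect_true(zres$significant)
  expect_equal(zres$observed, 20L)

  # absent category: degenerate, flagged
  absent <- planted[0]
  absent2 <- data.table::data.table(protein_id = "P99", category = "motif",
                                    start = 1L, end = 5L)
  zres2 <- enrichment_zscores(regions, placements, absent2)
  expect_equal(zres2$observed, 0L)
  expect_true(zres2$degenerate)
  expect_true(is.na(zres2$z))

  # saturating category: observed equals the randomized mean exactly
  full <- data.table::data.table(protein_id = names(lengths),
                                 category = "domain", start = 1L, end = 400L)
  zres3 <- enrichment_zscores(regions, placements, full)
  expect_equal(zres3$observed, zres3$random_mean)
  expect_true(zres3$degenerate)
})

test_that("the z threshold constant corresponds to one-sided p < 0.01", {
  expect_equal(stats::qnorm(0.99), 2.326, tolerance = 2e-4)
})
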