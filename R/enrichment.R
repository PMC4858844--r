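#' Smooth a per-residue disorder score track into binary calls
#'
#' The primary score track is smoothed with a centered moving average over
#' `window` residues (windows truncate at the termini).  A residue is
#' called disordered when the smoothed primary score exceeds `threshold`
#' or the raw binding-region score exceeds `threshold`, unless it lies
#' inside an interval annotated as a structured domain, which overrides
#' the disorder call.
#'
#' @param raw numeric vector of per-residue scores in `[0, 1]`
#' @param window odd smoothing window in residues (default 31)
#' @param threshold disorder call threshold (default 0.5, strict `>`)
#' @param binding optional raw binding-region score track, same length
#' @param domain_intervals optional data.frame/matrix with `start`, `end`
#'   columns of domain intervals (1-based inclusive)
#' @return logical vector of per-residue disorder calls
#' @export
smooth_disorder <- function(raw, window = 31L, threshold = 0.5,
                            binding = NULL, domain_intervals = NULL) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  L <- length(raw)
  if (!is.null(binding) && length(binding) != L) {
    stop("binding track length must match the primary track")
  }
  h <- (window - 1L) %/% 2L
  # truncated centered moving average via cumulative sums
  cs <- cumsum(c(0, raw))
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  smoothed <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  calls <- smoothed > threshold
  if (!is.null(binding)) calls <- calls | binding > threshold
  if (!is.null(domain_intervals) && NROW(domain_intervals) > 0L) {
    dom <- data.table::as.data.table(domain_intervals)
    for (i in seq_len(nrow(dom))) {
      s <- max(1L, dom$start[i]); e <- min(L, dom$end[i])
      if (s <= e) calls[s:e] <- FALSE
    }
  }
  calls
}

#' Fraction of residues called disordered
#'
#' @param calls logical vector from [smooth_disorder()]
#' @return fraction in `[0, 1]` (0 for a zero-length track)
#' @export
disorder_content <- function(calls) {
  if (length(calls) == 0L) return(0)
  mean(calls)
}

# Relative closeness within tolerance, with an absolute fallback for
# near-zero disorder contents (a fully ordered protein would otherwise
# match nothing).
within_tolerance <- function(target, source, tolerance, abs_floor = NA) {
  if (!is.na(abs_floor) && source < abs_floor) {
    abs(target - source) <= abs_floor
  } else {
    abs(target - source) <= tolerance * source
  }
}

#' Randomly re-place regions on matched proteins
#'
#' Each region is moved, independently in each of `n` randomizations, to a
#' protein drawn uniformly from those whose length and disorder content
#' are each within `tolerance` (relative) of the source protein's, and to
#' a start position drawn uniformly among starts that keep the region
#' inside the target.  Disorder contents below 0.05 are matched with an
#' absolute +/-0.05 band instead of the relative one.  Draws are
#' region-major (all randomizations of region 1, then region 2, ...) from
#' a single seeded generator, so runs are reproducible bit for bit.
#'
#' @param regions data.table with `protein_id` (or `isoform_id`), `start`,
#'   `end`
#' @param proteome data.table with `protein_id`, `length`,
#'   `disorder_content`
#' @param tolerance relative matching tolerance (default 0.1)
#' @param n number of randomizations (default 1000)
#' @param rng_seed integer seed
#' @return list(`placements` data.table with `rand`, `region`,
#'   `protein_id`, `start`, `end`; `skipped` data.table of regions with no
#'   eligible target and the randomization they were skipped in)
#' @export
randomize_placements <- function(regions, proteome, tolerance = 0.1,
                                 n = 1000L, rng_seed = 1L) {
  regions <- data.table::as.data.table(regions)
  if ("isoform_id" %in% names(regions) && !"protein_id" %in% names(regions)) {
    regions <- data.table::copy(regions)
    data.table::setnames(regions, "isoform_id", "protein_id")
  }
  proteome <- data.table::as.data.table(proteome)
  set.seed(rng_seed)
  placements <- vector("list", nrow(regions))
  skipped <- list()
  for (i in seq_len(nrow(regions))) {
    src <- proteome[protein_id == regions$protein_id[i]]
    if (nrow(src) == 0L) stop("region protein absent from proteome: ",
                              regions$protein_id[i])
    w <- regions$end[i] - regions$start[i] + 1L
    ok_len <- abs(proteome$length - src$length) <= tolerance * src$length
    ok_dis <- vapply(proteome$disorder_content, within_tolerance,
                     logical(1), source = src$disorder_content,
                     tolerance = tolerance, abs_floor = 0.05)
    eligible <- proteome[ok_len & ok_dis & proteome$length >= w]
    if (nrow(eligible) == 0L) {
      skipped[[length(skipped) + 1L]] <- data.table::data.table(
        region = i, protein_id = regions$protein_id[i], n_skipped = n
      )
      next
    }
    tgt <- eligible[sample.int(nrow(eligible), n, replace = TRUE)]
    starts <- floor(stats::runif(n) * (tgt$length - w + 1)) + 1L
    placements[[i]] <- data.table::data.table(
      rand = seq_len(n), region = i, protein_id = tgt$protein_id,
      start = as.integer(starts), end = as.integer(starts) + w - 1L
    )
  }
  list(placements = data.table::rbindlist(placements),
       skipped = data.table::rbindlist(skipped))
}

# number of intervals in `query` overlapping >= 1 interval of `subject`,
# and the total residues of `query` covered; optionally grouped by column
# `by` of `query`.  The subject is reduced per protein first so coverage
# widths never double-count.
overlap_stats <- function(query, subject, by = NULL) {
  if (nrow(query) == 0L) {
    return(data.table::data.table(n_regions = 0L, n_residues = 0L))
  }
  levels <- sort(unique(c(query$protein_id, subject$protein_id)))
  q_gr <- protein_granges(query$protein_id, query$start, query$end, levels)
  hit <- rep(FALSE, nrow(query))
  cov <- rep(0L, nrow(query))
  if (nrow(subject) > 0L) {
    s_gr <- GenomicRanges::reduce(protein_granges(
      subject$protein_id, subject$start, subject$end, levels
    ))
    hit <- IRanges::overlapsAny(q_gr, s_gr)
    ov <- GenomicRanges::findOverlaps(q_gr, s_gr)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov)
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(q_gr)[qh],
        IRanges::ranges(s_gr)[S4Vectors::subjectHits(ov)]
      ))
      agg <- data.table::data.table(q = qh, w = w)[, .(w = sum(w)), by = q]
      cov[agg$q] <- agg$w
    }
  }
  if (is.null(by)) {
    data.table::data.table(n_regions = sum(hit), n_residues = sum(cov))
  } else {
    data.table::data.table(g = query[[by]], hit = hit, cov = cov)[
      , .(n_regions = sum(hit), n_residues = sum(cov)), by = g]
  }
}

#' Annotation enrichment z-scores for called regions
#'
#' For each annotation category the observed overlap (number of regions
#' intersecting at least one interval of the category) is compared with
#' its distribution over the randomized placements; over- or
#' under-representation is reported in standard-deviation units
#' `z = (observed - mean) / sd`.  `|z| >= 2.326` corresponds to one-sided
#' p < 0.01 under normality of the randomized overlap counts and is
#' reported as the `significant` flag.  A residue-level overlap statistic
#' (total region residues covered by the category) is computed alongside
#' for comparison.
#'
#' @param regions data.table with `protein_id`/`isoform_id`, `start`, `end`
#' @param placements result of [randomize_placements()]
#' @param tracks data.table of annotation intervals with `protein_id`,
#'   `category`, `start`, `end`
#' @param z_threshold significance threshold in sd units (default 2.326)
#' @return data.table with one row per category: `category`, `observed`,
#'   `random_mean`, `random_sd`, `z`, `significant`, `observed_residues`,
#'   `random_mean_residues`, `random_sd_residues`, `z_residues`,
#'   `n_randomizations`, `degenerate` (TRUE when sd is 0 and z undefined)
#' @export
enrichment_zscores <- function(regions, placements, tracks,
                               z_threshold = 2.326) {
  regions <- data.table::as.data.table(regions)
  if ("isoform_id" %in% names(regions) && !"protein_id" %in% names(regions)) {
    regions <- data.table::copy(regions)
    data.table::setnames(regions, "isoform_id", "protein_id")
  }
  tracks <- data.table::as.data.table(tracks)
  placed <- placements$placements
  n_rand <- if (nrow(placed)) max(placed$rand) else 0L
  out <- lapply(sort(unique(tracks$category)), function(cat) {
    sub <- tracks[category == cat]
    obs <- overlap_stats(regions, sub)
    per_rand <- overlap_stats(placed, sub, by = "rand")
    # randomizations where every region was skipped still count as zeros
    counts <- residues <- numeric(n_rand)
    if (nrow(placed)) {
      counts[per_rand$g] <- per_rand$n_regions
      residues[per_rand$g] <- per_rand$n_residues
    }
    mu <- mean(counts); sdv <- stats::sd(counts)
    mu_r <- mean(residues); sd_r <- stats::sd(residues)
    degenerate <- !is.finite(sdv) || sdv == 0
    data.table::data.table(
      category = cat,
      observed = obs$n_regions,
      random_mean = mu, random_sd = sdv,
      z = if (degenerate) NA_real_ else (obs$n_regions - mu) / sdv,
      significant = if (degenerate) NA else
        abs((obs$n_regions - mu) / sdv) >= z_threshold,
      observed_residues = obs$n_residues,
      random_mean_residues = mu_r, random_sd_residues = sd_r,
      z_residues = if (!is.finite(sd_r) || sd_r == 0) NA_real_ else
        (obs$n_residues - mu_r) / sd_r,
      n_randomizations = n_rand,
      degenerate = degenerate
    )
  })
  data.table::rbindlist(out)
}
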