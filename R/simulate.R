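#' The default cancer-type vocabulary
#'
#' Twenty-seven standardized cancer-type labels used as the default
#' vocabulary for mutation annotation and for the synthetic cohort
#' generator.
#'
#' @return character vector of 27 labels
#' @export
cancer_type_vocabulary <- function() {
  c("Bladder cancer", "Acute myeloid leukemia", "Chronic myeloid leukemia",
    "Lymphoma", "Bone cancer", "Glioblastoma", "Neuroblastoma", "Glioma",
    "Medulloblastoma", "Breast cancer", "Cervical cancer",
    "Colorectal cancer", "Esophageal cancer", "Thyroid cancer",
    "Head and neck carcinoma", "Renal cell carcinoma",
    "Hepatocellular carcinoma", "Small cell lung cancer",
    "Non-small cell lung cancer", "Ovarian cancer", "Pancreatic cancer",
    "Prostate cancer", "Melanoma", "Squamous cell carcinoma",
    "Basal cell carcinoma", "Stomach cancer", "Endometrial cancer")
}

#' Specification of a synthetic mutation cohort
#'
#' Describes a cohort of genes with a uniform per-gene mutation
#' background, optional planted hotspots, and optional filter
#' confounders, from which [simulate_cohort()] generates all pipeline
#' inputs.
#'
#' @param n_genes number of genes
#' @param length_range `c(min, max)` of (uniformly drawn) protein lengths
#' @param background_rate expected background events per residue over the
#'   whole cohort (default 0.01)
#' @param plants list of hotspot plants, each a list with `gene` (index),
#'   `start`, `width`, `fold` (rate multiplier >= 1), and optionally
#'   `type_mix` (named probabilities over missense/insertion/deletion)
#' @param type_mix background mutation-type probabilities; the default
#'   puts ~97.6% of events on missense, matching the relative abundance
#'   of point mutations versus in-frame indels in large somatic cohorts
#' @param n_hypermutated number of hypermutated confounder samples
#' @param hypermutated_burden events per hypermutated sample (default 150)
#' @param n_clonal_pairs clonal duplicate sample pairs (6 events each,
#'   5 shared)
#' @param n_snp_events missense events placed on positions listed in the
#'   generated SNP exclusion table
#' @param n_low_complexity_events events placed inside generated
#'   low-complexity intervals
#' @param cancer_types label vocabulary sampled uniformly for each event
#' @param nonuniform_background when TRUE the background intensity varies
#'   along each sequence (linear ramp, 4x between the two termini) --- an
#'   adversarial mode used to characterize robustness of the caller, not
#'   a condition it is expected to pass under
#' @param rng_seed integer seed; all randomness flows from it through one
#'   pre-drawn sub-seed per gene, so adding genes does not perturb the
#'   draws of earlier genes
#' @return object of class `sim_spec`
#' @export
sim_spec <- function(n_genes = 10L, length_range = c(400L, 1200L),
                     background_rate = 0.01, plants = list(),
                     type_mix = c(missense = 0.976, insertion = 0.008,
                                  deletion = 0.016),
                     n_hypermutated = 0L, hypermutated_burden = 150L,
                     n_clonal_pairs = 0L, n_snp_events = 0L,
                     n_low_complexity_events = 0L,
                     cancer_types = cancer_type_vocabulary(),
                     nonuniform_background = FALSE,
                     rng_seed = 1L) {
  stopifnot(n_genes >= 1L, background_rate >= 0,
            length(length_range) == 2L, length_range[1] <= length_range[2])
  for (pl in plants) {
    stopifnot(pl$gene >= 1L, pl$gene <= n_genes, pl$fold >= 1,
              pl$start >= 1L, pl$width >= 1L)
  }
  type_mix <- type_mix[MUTATION_TYPES]
  type_mix <- type_mix / sum(type_mix)
  structure(list(n_genes = as.integer(n_genes),
                 length_range = as.integer(length_range),
                 background_rate = background_rate, plants = plants,
                 type_mix = type_mix,
                 n_hypermutated = as.integer(n_hypermutated),
                 hypermutated_burden = as.integer(hypermutated_burden),
                 n_clonal_pairs = as.integer(n_clonal_pairs),
                 n_snp_events = as.integer(n_snp_events),
                 n_low_complexity_events = as.integer(n_low_complexity_events),
                 cancer_types = cancer_types,
                 nonuniform_background = isTRUE(nonuniform_background),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_spec")
}

# draw one element of x (safe for length-1 x, unlike sample())
sample1 <- function(x) x[sample.int(length(x), 1L)]

random_protein <- function(L) {
  paste(sample(AA20, L, replace = TRUE), collapse = "")
}

# one mutation row; missense ref taken from the sequence, alt differs
sim_event <- function(gene_id, isoform_id, seq, pos, mtype, sample_id,
                      cancer_type) {
  L <- nchar(seq)
  if (mtype == "missense") {
    ref <- substr(seq, pos, pos)
    alt <- sample(setdiff(AA20, ref), 1L)
    data.table::data.table(gene_id = gene_id, isoform_id = isoform_id,
                           sample_id = sample_id, start = pos, end = pos,
                           mtype = mtype, ref_aa = ref, alt_aa = alt,
                           cancer_type = cancer_type)
  } else if (mtype == "insertion") {
    data.table::data.table(gene_id = gene_id, isoform_id = isoform_id,
                           sample_id = sample_id, start = pos, end = pos,
                           mtype = mtype, ref_aa = "",
                           alt_aa = sample(AA20, 1L),
                           cancer_type = cancer_type)
  } else {
    w <- min(sample(1:5, 1L), L - pos + 1L)
    data.table::data.table(gene_id = gene_id, isoform_id = isoform_id,
                           sample_id = sample_id, start = pos,
                           end = pos + w - 1L, mtype = mtype,
                           ref_aa = substr(seq, pos, pos), alt_aa = "",
                           cancer_type = cancer_type)
  }
}

sim_events_at <- function(gene_id, isoform_id, seq, positions, type_mix,
                          sample_ids, cancer_types_pool) {
  n <- length(positions)
  if (n == 0L) return(NULL)
  L <- nchar(seq)
  types <- sample(MUTATION_TYPES, n, replace = TRUE, prob = type_mix)
  labels <- sample(cancer_types_pool, n, replace = TRUE)
  starts <- as.integer(positions)
  ends <- starts
  ref <- character(n); alt <- character(n)
  mis <- types == "missense"
  if (any(mis)) {
    ref[mis] <- substring(seq, starts[mis], starts[mis])
    a <- sample(AA20, sum(mis), replace = TRUE)
    clash <- a == ref[mis]
    a[clash] <- AA20[match(ref[mis][clash], AA20) %% 20L + 1L]
    alt[mis] <- a
  }
  ins <- types == "insertion"
  if (any(ins)) alt[ins] <- sample(AA20, sum(ins), replace = TRUE)
  del <- types == "deletion"
  if (any(del)) {
    w <- pmin(sample(1:5, sum(del), replace = TRUE), L - starts[del] + 1L)
    ends[del] <- starts[del] + w - 1L
    ref[del] <- substring(seq, starts[del], starts[del])
  }
  data.table::data.table(gene_id = gene_id, isoform_id = isoform_id,
                         sample_id = sample_ids, start = starts, end = ends,
                         mtype = types, ref_aa = ref, alt_aa = alt,
                         cancer_type = labels)
}

#' Simulate a complete synthetic cohort
#'
#' Generates protein sequences, a mutation table, exclusion inputs and a
#' truth table of planted hotspots according to a [sim_spec()].
#' Background events are placed uniformly along each gene with count
#' `Poisson(length x background_rate)`; each plant adds
#' `Poisson(width x background_rate x fold)` events uniformly within its
#' interval.  Every non-confounder event gets its own sample ID so the
#' cleaning filters are not triggered spuriously; confounder samples are
#' constructed to trigger each filter exactly as specified.  Output is
#' deterministic given `rng_seed`.
#'
#' @param spec a [sim_spec()]
#' @return list with `sequences` (named character, isoform IDs),
#'   `mutations` (data.table), `exclusions` (list as in
#'   [read_exclusions()]), `truth` (data.table of plants with
#'   `gene_id`, `start`, `end`, `fold`, `n_planted`), and `spec`
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$rng_seed)
  gene_seeds <- sample.int(.Machine$integer.max, spec$n_genes + 1L)
  gene_ids <- sprintf("GENE%04d", seq_len(spec$n_genes))
  isoform_ids <- paste0(gene_ids, ".1")
  plants_by_gene <- split(spec$plants,
                          vapply(spec$plants, `[[`, numeric(1), "gene"))
  sequences <- character(spec$n_genes)
  per_gene <- vector("list", spec$n_genes)
  truth <- list()
  sample_counter <- 0L
  for (g in seq_len(spec$n_genes)) {
    set.seed(gene_seeds[g])
    L <- sample1(seq(spec$length_range[1], spec$length_range[2]))
    for (pl in plants_by_gene[[as.character(g)]]) {
      if (pl$start + pl$width - 1L > L) {
        stop("plant exceeds gene bounds in gene ", g)
      }
    }
    seq_g <- random_protein(L)
    sequences[g] <- seq_g
    n_bg <- stats::rpois(1L, L * spec$background_rate)
    bg_pos <- if (spec$nonuniform_background) {
      # linear intensity ramp, 4x between termini
      sample.int(L, n_bg, replace = TRUE, prob = 1 + 3 * (seq_len(L) - 1) / max(1L, L - 1L))
    } else {
      sample.int(L, n_bg, replace = TRUE)
    }
    rows <- list(sim_events_at(
      gene_ids[g], isoform_ids[g], seq_g, bg_pos, spec$type_mix,
      sprintf("S%07d", sample_counter + seq_len(n_bg)), spec$cancer_types
    ))
    sample_counter <- sample_counter + n_bg
    for (pl in plants_by_gene[[as.character(g)]]) {
      lambda <- pl$width * spec$background_rate * pl$fold
      n_pl <- stats::rpois(1L, lambda)
      pos <- pl$start + sample.int(pl$width, n_pl, replace = TRUE) - 1L
      mix <- if (!is.null(pl$type_mix)) {
        m <- pl$type_mix[MUTATION_TYPES]
        m[is.na(m)] <- 0
        m / sum(m)
      } else spec$type_mix
      rows[[length(rows) + 1L]] <- sim_events_at(
        gene_ids[g], isoform_ids[g], seq_g, pos, mix,
        sprintf("S%07d", sample_counter + seq_len(n_pl)), spec$cancer_types
      )
      sample_counter <- sample_counter + n_pl
      truth[[length(truth) + 1L]] <- data.table::data.table(
        gene_id = gene_ids[g], isoform_id = isoform_ids[g],
        start = pl$start, end = pl$start + pl$width - 1L,
        fold = pl$fold, n_planted = n_pl
      )
    }
    per_gene[[g]] <- data.table::rbindlist(rows)
  }
  names(sequences) <- isoform_ids
  mutations <- data.table::rbindlist(per_gene)

  # ---- confounders, drawn from their own sub-seed ----
  set.seed(gene_seeds[spec$n_genes + 1L])
  snp <- data.table::data.table(isoform_id = character(0), position = integer(0))
  lc <- data.table::data.table(isoform_id = character(0),
                               start = integer(0), end = integer(0))
  conf <- list()
  pick_gene <- function() sample.int(spec$n_genes, 1L)
  if (spec$n_hypermutated > 0L) {
    for (h in seq_len(spec$n_hypermutated)) {
      sid <- sprintf("HYPER%03d", h)
      for (i in seq_len(spec$hypermutated_burden)) {
        g <- pick_gene()
        pos <- sample.int(nchar(sequences[g]), 1L)
        conf[[length(conf) + 1L]] <- sim_event(
          gene_ids[g], isoform_ids[g], sequences[g], pos, "missense", sid,
          sample(spec$cancer_types, 1L)
        )
      }
    }
  }
  if (spec$n_clonal_pairs > 0L) {
    for (cp in seq_len(spec$n_clonal_pairs)) {
      sa <- sprintf("CLONE%03dA", cp); sb <- sprintf("CLONE%03dB", cp)
      g <- pick_gene()
      shared_pos <- sample.int(nchar(sequences[g]), 5L)
      shared <- data.table::rbindlist(lapply(shared_pos, function(p) {
        sim_event(gene_ids[g], isoform_ids[g], sequences[g], p, "missense",
                  sa, sample(spec$cancer_types, 1L))
      }))
      shared_b <- data.table::copy(shared)[, sample_id := sb]
      own <- lapply(c(sa, sb), function(sid) {
        gg <- pick_gene()
        sim_event(gene_ids[gg], isoform_ids[gg], sequences[gg],
                  sample.int(nchar(sequences[gg]), 1L), "missense", sid,
                  sample(spec$cancer_types, 1L))
      })
      conf[[length(conf) + 1L]] <- data.table::rbindlist(
        c(list(shared, shared_b), own)
      )
    }
  }
  if (spec$n_snp_events > 0L) {
    for (i in seq_len(spec$n_snp_events)) {
      g <- pick_gene()
      pos <- sample.int(nchar(sequences[g]), 1L)
      conf[[length(conf) + 1L]] <- sim_event(
        gene_ids[g], isoform_ids[g], sequences[g], pos, "missense",
        sprintf("SNPS%04d", i), sample(spec$cancer_types, 1L)
      )
      snp <- rbind(snp, data.table::data.table(isoform_id = isoform_ids[g],
                                               position = pos))
    }
  }
  if (spec$n_low_complexity_events > 0L) {
    for (i in seq_len(spec$n_low_complexity_events)) {
      g <- pick_gene()
      L <- nchar(sequences[g])
      s <- sample.int(max(1L, L - 20L), 1L)
      e <- min(L, s + 19L)
      pos <- sample1(seq(s, e))
      conf[[length(conf) + 1L]] <- sim_event(
        gene_ids[g], isoform_ids[g], sequences[g], pos, "missense",
        sprintf("LCS%04d", i), sample(spec$cancer_types, 1L)
      )
      lc <- rbind(lc, data.table::data.table(isoform_id = isoform_ids[g],
                                             start = s, end = e))
    }
  }
  if (length(conf)) {
    mutations <- data.table::rbindlist(c(list(mutations), conf))
  }
  list(sequences = sequences, mutations = mutations[],
       exclusions = list(snp_positions = snp, low_complexity = lc),
       truth = if (length(truth)) data.table::rbindlist(truth) else
         data.table::data.table(gene_id = character(0), isoform_id = character(0),
                                start = integer(0), end = integer(0),
                                fold = numeric(0), n_planted = integer(0)),
       spec = spec)
}

#' Write a simulated cohort to disk
#'
#' Emits `proteins.fasta`, `mutations.tsv`, `snp_positions.tsv`,
#' `low_complexity.tsv` and `truth.tsv` under `dir`.
#'
#' @param cohort result of [simulate_cohort()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aa <- Biostrings::AAStringSet(cohort$sequences)
  Biostrings::writeXStringSet(aa, file.path(dir, "proteins.fasta"))
  data.table::fwrite(cohort$mutations, file.path(dir, "mutations.tsv"), sep = "\t")
  data.table::fwrite(cohort$exclusions$snp_positions,
                     file.path(dir, "snp_positions.tsv"), sep = "\t")
  data.table::fwrite(cohort$exclusions$low_complexity,
                     file.path(dir, "low_complexity.tsv"), sep = "\t")
  data.table::fwrite(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t")
  invisible(dir)
}

#' Simulate annotation and disorder tracks for a proteome
#'
#' Generates interval annotations (domains, motifs, sites) and blocky
#' per-residue disorder score tracks for each protein.  With
#' `effect > 1` and a region table supplied, an extra interval of each
#' category is placed overlapping each region with probability
#' `1 - 1/effect`, building in co-localization at a controlled strength;
#' `effect = 1` yields a null proteome with no region/annotation
#' association.
#'
#' @param lengths named integer vector protein_id -> length
#' @param regions optional data.table with `protein_id`/`isoform_id`,
#'   `start`, `end` used for co-localization
#' @param effect co-localization strength (odds-style multiplier >= 1)
#' @param categories category names; interval geometry cycles through
#'   domain-like (mean 80 aa), motif-like (mean 8 aa) and site-like (1 aa)
#' @param rng_seed integer seed
#' @return list with `tracks` (data.table protein_id/category/start/end),
#'   `disorder` (data.table protein_id/position/score/binding_score) and
#'   `domains` (the domain-category intervals, for the disorder override)
#' @export
simulate_annotation_tracks <- function(lengths, regions = NULL, effect = 1,
                                       categories = c("domain", "motif", "site"),
                                       rng_seed = 1L) {
  stopifnot(effect >= 1)
  set.seed(rng_seed)
  if (!is.null(regions)) {
    regions <- data.table::as.data.table(regions)
    if ("isoform_id" %in% names(regions) && !"protein_id" %in% names(regions)) {
      data.table::setnames(regions, "isoform_id", "protein_id")
    }
  }
  mean_width <- function(cat) switch(
    cat, domain = 80, motif = 8, site = 1,
    c(80, 8, 1)[(match(cat, categories) - 1L) %% 3L + 1L]
  )
  tracks <- list()
  disorder <- list()
  for (pid in names(lengths)) {
    L <- lengths[[pid]]
    for (cat in categories) {
      mw <- mean_width(cat)
      lam <- L / 400  # about one domain-scale annotation per 400 aa
      k <- stats::rpois(1L, lam)
      if (k > 0L) {
        w <- pmax(1L, pmin(L, stats::rpois(k, mw)))
        s <- vapply(w, function(wi) sample.int(max(1L, L - wi + 1L), 1L),
                    integer(1))
        tracks[[length(tracks) + 1L]] <- data.table::data.table(
          protein_id = pid, category = cat, start = s, end = pmin(L, s + w - 1L)
        )
      }
      if (effect > 1 && !is.null(regions)) {
        reg_p <- regions[protein_id == pid]
        for (r in seq_len(nrow(reg_p))) {
          if (stats::runif(1) < 1 - 1 / effect) {
            wi <- max(1L, min(L, stats::rpois(1L, mw)))
            anchor <- sample1(seq(reg_p$start[r], reg_p$end[r]))
            s <- max(1L, anchor - sample.int(wi, 1L) + 1L)
            tracks[[length(tracks) + 1L]] <- data.table::data.table(
              protein_id = pid, category = cat, start = s,
              end = min(L, s + wi - 1L)
            )
          }
        }
      }
    }
    # blocky disorder architecture: alternating segments, ~40% disordered
    pos <- 1L
    score <- numeric(L); binding <- numeric(L)
    while (pos <= L) {
      seg <- min(L - pos + 1L, 10L + stats::rgeom(1L, 1 / 50))
      dis <- stats::runif(1) < 0.4
      idx <- seq(pos, pos + seg - 1L)
      score[idx] <- if (dis) stats::rbeta(seg, 8, 2) else stats::rbeta(seg, 2, 8)
      binding[idx] <- if (dis) stats::rbeta(seg, 4, 6) else stats::rbeta(seg, 1, 9)
      pos <- pos + seg
    }
    disorder[[length(disorder) + 1L]] <- data.table::data.table(
      protein_id = pid, position = seq_len(L), score = score,
      binding_score = binding
    )
  }
  tracks <- if (length(tracks)) data.table::rbindlist(tracks) else
    data.table::data.table(protein_id = character(0), category = character(0),
                           start = integer(0), end = integer(0))
  list(tracks = tracks,
       disorder = data.table::rbindlist(disorder),
       domains = tracks[category == "domain"])
}
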