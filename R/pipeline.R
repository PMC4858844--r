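#' Default pipeline configuration
#'
#' All tunable thresholds surfaced as named keys with their default
#' values: cleaning thresholds (`max_per_sample` 100, `clonal_min_mut` 5,
#' `clonal_share` 0.5), the scan (`seed_lengths` 7/10/30, `alpha` 0.01,
#' `tier_bounds` 1e-20/1e-5, `min_fraction` 0.2), disorder smoothing
#' (`disorder_window` 31, `disorder_threshold` 0.5) and the randomization
#' test (`tolerance` 0.1, `n_randomizations` 1000, `z_threshold` 2.326,
#' `rng_seed`).
#'
#' @param ... overrides of the default keys
#' @return named list
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    max_per_sample = 100L, clonal_min_mut = 5L, clonal_share = 0.5,
    seed_lengths = c(7L, 10L, 30L), alpha = 0.01,
    tier_bounds = c(1e-20, 1e-5), min_fraction = 0.2,
    disorder_window = 31L, disorder_threshold = 0.5,
    tolerance = 0.1, n_randomizations = 1000L, z_threshold = 2.326,
    rng_seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Per-protein disorder content from raw score tracks
#'
#' Applies [smooth_disorder()] to each protein's score track (with the
#' domain override) and returns the proteome table used by
#' [randomize_placements()].
#'
#' @param disorder data.table with `protein_id`, `position`, `score` and
#'   optionally `binding_score`
#' @param domains optional data.table of domain intervals
#'   (`protein_id`, `start`, `end`)
#' @param lengths named integer vector protein_id -> length; defaults to
#'   the maximum annotated position per protein
#' @param window,threshold smoothing parameters (defaults 31, 0.5)
#' @return data.table with `protein_id`, `length`, `disorder_content`
#' @export
disorder_proteome <- function(disorder, domains = NULL, lengths = NULL,
                              window = 31L, threshold = 0.5) {
  disorder <- data.table::as.data.table(disorder)
  if (!is.null(domains)) domains <- data.table::as.data.table(domains)
  ids <- unique(disorder$protein_id)
  out <- lapply(ids, function(pid) {
    tr <- disorder[protein_id == pid][order(position)]
    L <- if (!is.null(lengths)) lengths[[pid]] else max(tr$position)
    score <- numeric(L)
    score[tr$position] <- tr$score
    binding <- NULL
    if ("binding_score" %in% names(tr)) {
      binding <- numeric(L)
      binding[tr$position] <- tr$binding_score
    }
    dom <- if (!is.null(domains)) domains[protein_id == pid] else NULL
    calls <- smooth_disorder(score, window, threshold, binding, dom)
    data.table::data.table(protein_id = pid, length = L,
                           disorder_content = disorder_content(calls))
  })
  data.table::rbindlist(out)
}

stage_counts <- function(label, n) list(stage = label, n_mutations = n)

#' Run the full pipeline: clean, call, enrich, substitution rates
#'
#' Wires the stages in fixed order on in-memory inputs and returns every
#' intermediate product together with a run manifest (version, config
#' snapshot, per-stage counts, filter reports, RNG seed).  The
#' enrichment stage runs only when annotation and disorder tracks are
#' supplied.  Given identical inputs, config and seed the outputs are
#' byte-identical across runs.
#'
#' @param mutations validated mutation data.table
#' @param sequences named character vector of isoform sequences
#' @param exclusions list from [read_exclusions()] (optional)
#' @param annotations annotation track data.table (optional)
#' @param disorder disorder score track data.table (optional)
#' @param config list from [pipeline_config()]
#' @return list with `cleaned`, `filter_reports`, `regions`,
#'   `enrichment` (or NULL), `substitutions`, `manifest`
#' @export
run_pipeline <- function(mutations, sequences, exclusions = NULL,
                         annotations = NULL, disorder = NULL,
                         config = pipeline_config()) {
  counts <- list(stage_counts("input", nrow(mutations)))
  cleaned <- clean_mutations(
    mutations, exclusions,
    max_per_sample = config$max_per_sample,
    min_mutations = config$clonal_min_mut,
    min_shared_fraction = config$clonal_share
  )
  counts <- c(counts, list(stage_counts("cleaned", nrow(cleaned$mutations))))
  gene_sets <- build_gene_sets(cleaned$mutations, sequences)
  sc <- scan_config(seed_lengths = config$seed_lengths, alpha = config$alpha,
                    tier_bounds = config$tier_bounds,
                    min_fraction = config$min_fraction)
  regions <- call_regions_cohort(gene_sets, sc)
  counts <- c(counts, list(list(stage = "regions", n_regions = nrow(regions))))
  enrichment <- NULL
  if (!is.null(annotations) && !is.null(disorder) && nrow(regions) > 0L) {
    lengths <- setNames(nchar(sequences), names(sequences))
    domains <- data.table::as.data.table(annotations)[category == "domain"]
    proteome <- disorder_proteome(disorder, domains, as.list(lengths),
                                  window = config$disorder_window,
                                  threshold = config$disorder_threshold)
    placements <- randomize_placements(
      regions, proteome, tolerance = config$tolerance,
      n = config$n_randomizations, rng_seed = config$rng_seed
    )
    enrichment <- enrichment_zscores(regions, placements, annotations,
                                     z_threshold = config$z_threshold)
  }
  subs <- substitution_percentages(dedupe_substitutions(cleaned$mutations),
                                   regions)
  manifest <- list(
    tool = "simpre",
    version = as.character(utils::packageVersion("simpre")),
    config = config,
    counts = counts,
    filter_reports = cleaned$reports,
    rng_seed = config$rng_seed
  )
  list(cleaned = cleaned$mutations, filter_reports = cleaned$reports,
       regions = regions, enrichment = enrichment, substitutions = subs,
       manifest = manifest)
}

#' Write pipeline outputs and the run manifest
#'
#' Emits `cleaned_mutations.tsv`, `regions.tsv`, `enrichment.tsv` (when
#' computed), `substitution_rates.tsv` and `manifest.json` (which also
#' records MD5 checksums of the emitted files).
#'
#' @param result list from [run_pipeline()]
#' @param out_dir output directory (created if missing)
#' @return `out_dir`, invisibly
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(dt, name) {
    p <- file.path(out_dir, name)
    data.table::fwrite(dt, p, sep = "\t")
    paths <<- c(paths, p)
  }
  w(result$cleaned, "cleaned_mutations.tsv")
  w(result$regions, "regions.tsv")
  if (!is.null(result$enrichment)) w(result$enrichment, "enrichment.tsv")
  subs <- result$substitutions
  sub_long <- data.table::rbindlist(list(
    substitution_long(subs$total, "total"),
    substitution_long(subs$inside, "inside"),
    substitution_long(subs$outside, "outside")
  ))
  w(sub_long, "substitution_rates.tsv")
  manifest <- result$manifest
  sums <- tools::md5sum(paths)
  names(sums) <- basename(paths)
  manifest$output_checksums <- as.list(sums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
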