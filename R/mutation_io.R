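#' @import data.table
#' @importFrom stats setNames
NULL

MUTATION_TYPES <- c("missense", "insertion", "deletion")

MUTATION_FIELDS <- c(
  "gene_id", "isoform_id", "sample_id", "start", "end",
  "mtype", "ref_aa", "alt_aa", "cancer_type"
)

#' Default column mapping for mutation tables
#'
#' Maps internal mutation fields to the column names expected in an input
#' TSV.  Override individual entries (e.g. from a YAML config) to ingest
#' tables with different headers.
#'
#' @param ... named overrides, e.g. `gene_id = "Gene name"`
#' @return named character vector field -> file column
#' @export
mutation_column_config <- function(...) {
  cfg <- setNames(MUTATION_FIELDS, MUTATION_FIELDS)
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), MUTATION_FIELDS)
    if (length(bad)) stop("unknown mutation fields: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}

normalize_mtype <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("missense", "substitution", "sub", "point")] <- "missense"
  x[x %in% c("insertion", "ins", "inframe_insertion")] <- "insertion"
  x[x %in% c("deletion", "del", "inframe_deletion")] <- "deletion"
  x
}

#' Read and validate a mutation table
#'
#' Reads a COSMIC-style flat TSV of somatic mutations (one row per event)
#' and validates every row against the mutation invariants: coordinates
#' 1-based with `start <= end`, a recognizable mutation type, and for
#' missense events `start == end` with differing reference and alternate
#' residues.  Rows failing validation are returned separately with their
#' 1-based data line number and a reason; valid rows keep their input
#' order.
#'
#' @param path TSV file with a header line
#' @param column_config mapping from [mutation_column_config()]; fields
#'   `ref_aa`, `alt_aa` and `cancer_type` are optional in the file and
#'   filled with `""` when their column is absent
#' @return list with elements `mutations` (data.table, one row per valid
#'   event) and `rejected` (data.table with `line` and `reason`)
#' @export
parse_mutation_table <- function(path, column_config = mutation_column_config()) {
  if (!file.exists(path)) stop("mutation table not found: ", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL)
  mandatory <- c("gene_id", "isoform_id", "sample_id", "start", "end", "mtype")
  missing_cols <- setdiff(column_config[mandatory], names(raw))
  if (length(missing_cols)) {
    stop("mutation table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dt <- data.table::data.table(line = seq_len(nrow(raw)))
  for (f in MUTATION_FIELDS) {
    col <- column_config[[f]]
    dt[[f]] <- if (col %in% names(raw)) raw[[col]] else ""
  }
  dt[, `:=`(start = suppressWarnings(as.integer(start)),
            end = suppressWarnings(as.integer(end)),
            mtype = normalize_mtype(mtype),
            ref_aa = toupper(trimws(ref_aa)),
            alt_aa = toupper(trimws(alt_aa)))]
  validate_mutations(dt)
}

#' Validate mutation rows against the coordinate and type invariants
#'
#' @param dt data.table with the mutation fields (and optionally a `line`
#'   column used in the rejection report)
#' @return list(`mutations`, `rejected`) as in [parse_mutation_table()]
#' @export
validate_mutations <- function(dt) {
  dt <- data.table::as.data.table(dt)
  if (!"line" %in% names(dt)) dt[, line := seq_len(.N)]
  reason <- rep(NA_character_, nrow(dt))
  bad_coord <- is.na(dt$start) | is.na(dt$end) | dt$start < 1L | dt$end < dt$start
  reason[bad_coord] <- "malformed coordinates (need 1 <= start <= end)"
  bad_type <- is.na(reason) & !(dt$mtype %in% MUTATION_TYPES)
  reason[bad_type] <- "unrecognized mutation type"
  bad_mis <- is.na(reason) & dt$mtype == "missense" &
    (dt$start != dt$end | (nzchar(dt$ref_aa) & nzchar(dt$alt_aa) & dt$ref_aa == dt$alt_aa))
  reason[bad_mis] <- "invalid missense record (start != end or ref == alt)"
  keep <- is.na(reason)
  rejected <- data.table::data.table(line = dt$line[!keep], reason = reason[!keep])
  mutations <- dt[keep, c(MUTATION_FIELDS), with = FALSE]
  list(mutations = mutations[], rejected = rejected[])
}

#' Load protein sequences from a FASTA file
#'
#' @param fasta_path FASTA of amino-acid sequences; record IDs are taken as
#'   the first whitespace-delimited token of each header
#' @return named character vector of upper-cased sequences
#' @export
load_sequences <- function(fasta_path) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' Drop mutations whose coordinates exceed their isoform's length
#'
#' @param mutations mutation data.table
#' @param lengths named integer vector isoform_id -> residue count (e.g.
#'   `nchar(load_sequences(...))`)
#' @return list(`mutations` kept rows, `rejected` data.table with reason;
#'   mutations on isoforms absent from `lengths` are rejected too)
#' @export
validate_against_lengths <- function(mutations, lengths) {
  mutations <- data.table::as.data.table(mutations)
  len <- unname(lengths[mutations$isoform_id])
  keep <- !is.na(len) & mutations$end <= len
  reason <- ifelse(is.na(len), "isoform not in sequence set",
                   "coordinate beyond sequence length")
  rejected <- data.table::data.table(
    line = which(!keep), reason = reason[!keep]
  )
  list(mutations = mutations[keep], rejected = rejected[])
}

#' Choose each gene's primary isoform by mutation count
#'
#' For every gene the isoform carrying the most mutations is selected as
#' the single analysis isoform; ties break to the lexicographically
#' smallest isoform ID so the choice is independent of row order.
#'
#' @param mutations mutation data.table with `gene_id` and `isoform_id`
#' @return named character vector gene_id -> chosen isoform_id
#' @export
select_primary_isoform <- function(mutations) {
  mutations <- data.table::as.data.table(mutations)
  if (nrow(mutations) == 0L) return(setNames(character(0), character(0)))
  counts <- mutations[, .N, by = .(gene_id, isoform_id)]
  data.table::setorder(counts, gene_id, -N, isoform_id)
  chosen <- counts[, .SD[1L], by = gene_id]
  setNames(chosen$isoform_id, chosen$gene_id)
}

#' Restrict a cohort to each gene's primary isoform
#'
#' @param mutations mutation data.table
#' @param primary mapping from [select_primary_isoform()]; computed from
#'   `mutations` when NULL
#' @return list(`mutations` retained rows, `n_dropped` count of mutations
#'   mapped only to non-primary isoforms)
#' @export
keep_primary_isoform <- function(mutations, primary = NULL) {
  mutations <- data.table::as.data.table(mutations)
  if (is.null(primary)) primary <- select_primary_isoform(mutations)
  keep <- mutations$isoform_id == unname(primary[mutations$gene_id])
  keep[is.na(keep)] <- FALSE
  list(mutations = mutations[keep], n_dropped = sum(!keep))
}

#' Bundle one gene's cleaned mutations with its chosen isoform
#'
#' @param gene_id,isoform_id identifiers
#' @param length residue count of the isoform sequence
#' @param mutations data.table of mutations on this isoform
#' @param sequence optional amino-acid string (needed only for
#'   substitution-rate context)
#' @return object of class `GeneMutationSet`
#' @export
gene_mutation_set <- function(gene_id, isoform_id, length, mutations,
                              sequence = NULL) {
  mutations <- data.table::as.data.table(mutations)
  stopifnot(length >= 1L)
  if (nrow(mutations)) {
    if (any(mutations$end > length)) {
      stop("mutation coordinates exceed isoform length for ", gene_id)
    }
    if (!all(mutations$isoform_id == isoform_id)) {
      stop("all mutations in a GeneMutationSet must share the isoform")
    }
  }
  structure(
    list(gene_id = gene_id, isoform_id = isoform_id,
         length = as.integer(length), mutations = mutations,
         sequence = sequence),
    class = "GeneMutationSet"
  )
}

#' @export
print.GeneMutationSet <- function(x, ...) {
  cat(sprintf("GeneMutationSet %s (isoform %s, %d aa): %d mutations\n",
              x$gene_id, x$isoform_id, x$length, nrow(x$mutations)))
  invisible(x)
}

#' Split a cleaned cohort into per-gene mutation sets
#'
#' Selects each gene's primary isoform, drops mutations mapped elsewhere,
#' validates coordinates against the sequences, and returns one
#' [gene_mutation_set()] per gene.
#'
#' @param mutations cleaned mutation data.table
#' @param sequences named character vector from [load_sequences()]
#' @return named list of `GeneMutationSet`, ordered by gene_id
#' @export
build_gene_sets <- function(mutations, sequences) {
  mutations <- data.table::as.data.table(mutations)
  lengths <- setNames(nchar(sequences), names(sequences))
  prim <- keep_primary_isoform(mutations)
  ok <- validate_against_lengths(prim$mutations, lengths)
  mut <- ok$mutations
  genes <- sort(unique(mut$gene_id))
  sets <- lapply(genes, function(g) {
    gm <- mut[gene_id == g]
    iso <- gm$isoform_id[1L]
    gene_mutation_set(g, iso, lengths[[iso]], gm, sequence = sequences[[iso]])
  })
  setNames(sets, genes)
}

#' Read exclusion inputs (common SNP positions, low-complexity intervals)
#'
#' @param snp_path TSV with columns `isoform_id`, `position` (or
#'   `isoform_id`, `start` treated as a single position); NULL for none
#' @param low_complexity_path TSV with columns `isoform_id`, `start`,
#'   `end`; NULL for none
#' @return list with `snp_positions` (data.table isoform_id/position) and
#'   `low_complexity` (data.table isoform_id/start/end)
#' @export
read_exclusions <- function(snp_path = NULL, low_complexity_path = NULL) {
  snp <- data.table::data.table(isoform_id = character(0), position = integer(0))
  if (!is.null(snp_path)) {
    snp <- data.table::fread(snp_path, sep = "\t", header = TRUE)
    if (!"position" %in% names(snp) && "start" %in% names(snp)) {
      data.table::setnames(snp, "start", "position")
    }
    snp <- snp[, .(isoform_id = as.character(isoform_id),
                   position = as.integer(position))]
  }
  lc <- data.table::data.table(isoform_id = character(0),
                               start = integer(0), end = integer(0))
  if (!is.null(low_complexity_path)) {
    lc <- data.table::fread(low_complexity_path, sep = "\t", header = TRUE)
    lc <- lc[, .(isoform_id = as.character(isoform_id),
                 start = as.integer(start), end = as.integer(end))]
    if (any(lc$start > lc$end)) stop("malformed low-complexity interval (start > end)")
  }
  list(snp_positions = snp, low_complexity = lc)
}

#' Write a mutation table to TSV
#'
#' @param mutations mutation data.table (may include extra columns such as
#'   `filter_reason`)
#' @param path output file
#' @export
write_mutation_table <- function(mutations, path) {
  data.table::fwrite(data.table::as.data.table(mutations), path, sep = "\t")
  invisible(path)
}
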