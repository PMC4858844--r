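#' One-sided exact enrichment p-value for a candidate region
#'
#' Computes the one-sided (enrichment) Fisher's exact p-value for the 2x2
#' contingency table
#'
#' \preformatted{
#'                 mutation events   residue positions
#'   inside region       m_in             len_in
#'   outside region      m_out            len_out
#' }
#'
#' i.e. the hypergeometric upper tail P(X >= m_in) where X counts mutation
#' events falling on the first row when row totals are fixed.  This is the
#' probability, under a uniform per-gene background, of observing at least
#' as many events inside an interval of `len_in` residues as were seen.
#'
#' All four arguments are vectorized and recycled to a common length.
#'
#' @param m_in number of mutation events overlapping the region
#' @param m_out number of mutation events outside the region (same gene)
#' @param len_in region length in residues (>= 1)
#' @param len_out residues of the protein outside the region (>= 0)
#' @return p-value(s) in (0, 1].  By convention `m_in == 0` or
#'   `len_out == 0` (region covers the whole protein) give 1: neither
#'   carries evidence of local enrichment.
#' @seealso [region_pvalue_binomial()] for the binomial-tail cross-check.
#' @export
region_pvalue <- function(m_in, m_out, len_in, len_out) {
  n <- max(length(m_in), length(m_out), length(len_in), length(len_out))
  m_in <- rep_len(as.numeric(m_in), n)
  m_out <- rep_len(as.numeric(m_out), n)
  len_in <- rep_len(as.numeric(len_in), n)
  len_out <- rep_len(as.numeric(len_out), n)
  if (any(m_in < 0 | m_out < 0 | len_out < 0)) {
    stop("counts and lengths must be non-negative")
  }
  if (any(len_in < 1)) stop("len_in must be >= 1")
  p <- rep(1, n)
  idx <- which(m_in > 0 & len_out > 0)
  if (length(idx)) {
    # white balls = mutation events, black balls = residue positions,
    # draw = first-row total; upper tail at the observed inside count
    p[idx] <- stats::phyper(
      m_in[idx] - 1,
      m = m_in[idx] + m_out[idx],
      n = len_in[idx] + len_out[idx],
      k = m_in[idx] + len_in[idx],
      lower.tail = FALSE
    )
  }
  pmin(p, 1)
}

#' Binomial-tail approximation to the region enrichment p-value
#'
#' Upper-tail binomial probability of seeing at least `m_in` of the gene's
#' events inside the region when each event lands inside independently with
#' probability `len_in / (len_in + len_out)`.  Kept as an independent
#' cross-check of [region_pvalue()]: the two agree closely whenever event
#' counts are small relative to the protein length, which is the regime the
#' scan operates in.
#'
#' @inheritParams region_pvalue
#' @return p-value(s) in (0, 1]
#' @export
region_pvalue_binomial <- function(m_in, m_out, len_in, len_out) {
  n <- max(length(m_in), length(m_out), length(len_in), length(len_out))
  m_in <- rep_len(as.numeric(m_in), n)
  m_out <- rep_len(as.numeric(m_out), n)
  len_in <- rep_len(as.numeric(len_in), n)
  len_out <- rep_len(as.numeric(len_out), n)
  p <- rep(1, n)
  idx <- which(m_in > 0 & len_out > 0)
  if (length(idx)) {
    p[idx] <- stats::pbinom(
      m_in[idx] - 1,
      size = m_in[idx] + m_out[idx],
      prob = len_in[idx] / (len_in[idx] + len_out[idx]),
      lower.tail = FALSE
    )
  }
  pmin(p, 1)
}
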