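# Independent exact-tail oracle: enumerates every more-extreme 2x2 table at
# fixed margins and sums table probabilities computed from log-binomial
# coefficients.  Deliberately avoids phyper/dhyper (the implementation path).
oracle_tail <- function(m_in, m_out, len_in, len_out) {
  if (m_in == 0 || len_out == 0) return(1)
  M <- m_in + m_out        # column total: mutation events
  L <- len_in + len_out    # column total: residue positions
  r1 <- m_in + len_in      # first-row total
  ks <- seq(max(0, r1 - L), min(M, r1))
  logp <- lchoose(M, ks) + lchoose(L, r1 - ks) - lchoose(M + L, r1)
  sum(exp(logp[ks >= m_in]))
}

# All-x tails for one margin family (N, r1, c1): returns data.frame of every
# feasible inside-count x with its upper-tail probability, by reverse
# cumulative sum of enumerated table probabilities.
oracle_family_tails <- function(N, r1, c1) {
  lo <- max(0L, r1 + c1 - N)
  hi <- min(r1, c1)
  ks <- seq(lo, hi)
  logp <- lchoose(c1, ks) + lchoose(N - c1, r1 - ks) - lchoose(N, r1)
  tails <- rev(cumsum(rev(exp(logp))))
  data.frame(x = ks, tail = pmin(tails, 1))
}
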