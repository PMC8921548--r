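# Brute-force hypergeometric oracle for the two-sided exact test on a 2x2
# carrier table (a = case carriers, b = case non-carriers, c = control
# carriers, d = control non-carriers): conditioning on all margins, sum the
# probabilities of every table as or less probable than the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c          # carriers
  n <- b + d          # non-carriers
  k <- a + b          # cases
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
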