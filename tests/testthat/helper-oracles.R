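# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Two-sided exact Mann-Whitney p by brute-force enumeration of all
# C(n_f + n_m, n_f) label assignments (no ties assumed): the probability of
# a U at least as far from its null mean as the observed one.
mw_enum_p <- function(values_f, values_m) {
  n_f <- length(values_f)
  pooled <- c(values_f, values_m)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n_f * (n_f + 1) / 2
  u_obs <- u_of(seq_len(n_f))
  centre <- n_f * length(values_m) / 2
  assigns <- utils::combn(length(pooled), n_f, simplify = FALSE)
  us <- vapply(assigns, u_of, numeric(1))
  mean(abs(us - centre) >= abs(u_obs - centre))
}

# Union length of a set of [start, end) intervals clipped to a query
# window, by an explicit sweep over sorted endpoints.
sweep_union_length <- function(starts, ends, qstart, qend) {
  s <- pmax(starts, qstart)
  e <- pmin(ends, qend)
  keep <- s < e
  s <- s[keep]
  e <- e[keep]
  if (!length(s)) return(0)
  o <- order(s)
  s <- s[o]
  e <- e[o]
  total <- 0
  cur_s <- s[1]
  cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- s[i]
      cur_e <- e[i]
    }
  }
  total + (cur_e - cur_s)
}

# Hypergeometric upper tail by direct pmf summation.
hyper_upper_oracle <- function(obs, n_sig, m_chr, m_total) {
  ks <- obs:min(n_sig, m_chr)
  sum(choose(m_chr, ks) * choose(m_total - m_chr, n_sig - ks)) /
    choose(m_total, n_sig)
}
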