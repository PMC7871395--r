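# Independent brute-force oracles. These deliberately share no code with the
# package internals: the scorer materializes every (gene, left, right)
# triple by walking the circle one position at a time, and the
# hypergeometric tail is computed by exhaustive enumeration of draws.

oracle_score_occurrences <- function(tokens, ref_tokens, mode = "ordered") {
  n <- length(tokens)
  rn <- length(ref_tokens)
  per <- integer(n)
  for (i in seq_len(n)) {
    g <- tokens[i]
    l <- tokens[if (i == 1) n else i - 1]
    r <- tokens[if (i == n) 1 else i + 1]
    j <- which(ref_tokens == g)
    stopifnot(length(j) == 1)
    L <- ref_tokens[if (j == 1) rn else j - 1]
    R <- ref_tokens[if (j == rn) 1 else j + 1]
    per[i] <- if (mode == "ordered") {
      (l != L) + (r != R)
    } else {
      2L - max((l == L) + (r == R), (l == R) + (r == L))
    }
  }
  per
}

oracle_score_genome <- function(tokens, ref_tokens, mode = "ordered") {
  sum(oracle_score_occurrences(tokens, ref_tokens, mode))
}

# P(X >= k) for X hypergeometric(N, K, n), by enumerating all C(N, n) draws
oracle_hyper_upper <- function(k, N, K, n) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}
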