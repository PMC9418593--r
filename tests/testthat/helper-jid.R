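## Brute-force kernel-sum oracle: double loop over cells x pairs.
bruteForceJid <- function(pairs, centers, bw) {
  lx <- log10(pairs[, 1]); ly <- log10(pairs[, 2])
  out <- matrix(0, length(centers), length(centers))
  for (i in seq_along(centers))
    for (j in seq_along(centers))
      for (p in seq_len(nrow(pairs)))
        out[i, j] <- out[i, j] +
          dnorm(centers[i] - lx[p], sd = bw) *
          dnorm(centers[j] - ly[p], sd = bw)
  out
}
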