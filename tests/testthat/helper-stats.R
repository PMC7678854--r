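# Literal brute-force oracle: enumerate all C(n1+n2, n1) labelings of the
# pooled midranks and tabulate the U distribution.
bruteForceMW <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  pLe <- mean(us <= uObs + 1e-9)
  pGe <- mean(us >= uObs - 1e-9)
  list(u = uObs, p = min(1, 2 * min(pLe, pGe)))
}

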