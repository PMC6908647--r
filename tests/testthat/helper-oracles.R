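# Independent brute-force oracles shared across test files.

# two-sided rank-sum p over all C(N, n1) group assignments, midrank ties
enum_wilcox_p <- function(x1, x2) {
  v <- c(x1, x2); n1 <- length(x1); N <- length(v)
  r <- rank(v)
  E <- n1 * mean(r)
  obs <- abs(sum(r[seq_len(n1)]) - E)
  splits <- combn(N, n1)
  hits <- 0
  for (j in seq_len(ncol(splits)))
    if (abs(sum(r[splits[, j]]) - E) >= obs - 1e-9) hits <- hits + 1
  hits / ncol(splits)
}

# mutual information of the binned joint distribution, in bits
oracle_ig <- function(x, y, n_bins) {
  bin <- pmin(pmax(floor(pmin(pmax(x, 0), 1) * n_bins) + 1, 1), n_bins)
  tab <- table(factor(bin, levels = 1:n_bins), y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  unname(mi)
}
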