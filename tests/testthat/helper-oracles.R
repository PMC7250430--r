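# Independent brute-force oracles used to cross-check the implementations.

# Kruskal-Wallis H from first principles: pooled mid-ranks, rank-sum formula,
# explicit tie correction.
brute_kruskal <- function(values, groups) {
  g <- factor(groups)
  N <- length(values)
  r <- rank(values, ties.method = "average")
  Rsum <- tapply(r, g, sum)
  n <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / n) - 3 * (N + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) return(list(H = 0, p = 1))
  H <- H / C
  list(H = H, p = stats::pchisq(H, nlevels(g) - 1, lower.tail = FALSE))
}

# Dunn z statistics from first principles (mean ranks, tie-corrected pooled
# variance, two-sided normal p).
brute_dunn <- function(values, groups) {
  g <- factor(groups)
  N <- length(values)
  r <- rank(values, ties.method = "average")
  mr <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(r)
  v <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- combn(levels(g), 2)
  data.frame(
    level_1 = pairs[1, ], level_2 = pairs[2, ],
    z = apply(pairs, 2, function(pr) {
      se <- sqrt(v * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
      if (se > 0) (mr[[pr[1]]] - mr[[pr[2]]]) / se else 0
    }),
    stringsAsFactors = FALSE
  )
}

# noiseless blank-subtracted series from known Richards parameters
truth_series <- function(a, k, d, xc, days = 30) {
  x <- seq.int(0, days - 1)
  list(x = x, y = richards(x, a, k, d, xc))
}

# a tiny plate design used by several IO / pipeline tests
tiny_design <- function(organisms = "demo", replicates = 2, days = 12) {
  plate_design(salinities = c(0, 30), phs = c(1, 7), temperatures = c(25, 45),
               replicates = replicates, organisms = organisms, days = days)
}
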