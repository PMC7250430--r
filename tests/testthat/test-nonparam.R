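test_that("normality screen separates normal from skewed samples", {
  set.seed(42)
  p_norm <- replicate(40, shapiro_wilk(rnorm(200))$p)
  p_exp <- replicate(40, shapiro_wilk(rexp(200))$p)
  expect_gte(mean(p_norm > 0.05), 0.90)
  expect_gte(mean(p_exp < 0.05), 0.99)
  expect_error(shapiro_wilk(c(1, 2)), "n >= 3")
})

test_that("Brown-Forsythe flags unequal variances and holds its size", {
  set.seed(43)
  # equal distributions: rejection near nominal
  rej <- replicate(200, {
    brown_forsythe(rnorm(100), rep(1:2, each = 50))$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.05)
  # variance ratio 100
  p_het <- replicate(50, {
    brown_forsythe(c(rnorm(50, 0, 1), rnorm(50, 0, 10)),
                   rep(1:2, each = 50))$p
  })
  expect_gte(mean(p_het < 0.001), 0.99)
  expect_error(brown_forsythe(rnorm(3), c(1, 1, 2)), "n >= 2")
  expect_warning(res <- brown_forsythe(rep(1, 10), rep(1:2, each = 5)),
                 "degenerate")
  expect_equal(res$p, 1)
})

test_that("Kruskal-Wallis matches a brute-force H computation on small instances", {
  # fixed textbook-style case: three separated triples
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(1:3, each = 3)
  expect_equal(kruskal_wallis(v, g)$statistic, 7.2)
  # randomized small instances, with ties, exact agreement
  set.seed(44)
  for (i in 1:50) {
    n <- sample(6:12, 1)
    k <- sample(2:3, 1)
    g <- sample(rep(seq_len(k), length.out = n))
    v <- sample(1:5, n, replace = TRUE)  # force ties
    if (length(unique(v)) == 1) next
    ours <- kruskal_wallis(v, g)
    oracle <- brute_kruskal(v, g)
    expect_equal(ours$statistic, oracle$H, tolerance = 1e-12)
    expect_equal(ours$p, oracle$p, tolerance = 1e-12)
  }
  # fully tied input is reported as no separation, not an error
  expect_equal(kruskal_wallis(c(3, 3, 3, 3), c(1, 1, 2, 2)),
               list(statistic = 0, df = 1, p = 1))
  expect_error(kruskal_wallis(1:3, factor(c(1, 1, 1), levels = 1:2)), "empty")
})

test_that("Dunn's test matches a brute-force mean-rank computation", {
  set.seed(45)
  for (i in 1:30) {
    n <- sample(6:12, 1)
    k <- sample(2:4, 1)
    g <- sample(rep(seq_len(k), length.out = n))
    v <- sample(1:6, n, replace = TRUE)
    ours <- dunn_test(v, g)
    oracle <- brute_dunn(v, g)
    expect_equal(ours$z, oracle$z, tolerance = 1e-12)
    expect_equal(ours$p, pmin(2 * pnorm(-abs(oracle$z)), 1), tolerance = 1e-12)
  }
})

test_that("Dunn orders separated groups sensibly and is symmetric for identical groups", {
  res <- dunn_test(c(1, 2, 3, 4, 5, 6, 7, 8, 9), rep(c("g1", "g2", "g3"), each = 3))
  zmag <- abs(res$z)
  extreme <- zmag[res$level_1 == "g1" & res$level_2 == "g3"]
  expect_true(all(extreme > zmag[!(res$level_1 == "g1" & res$level_2 == "g3")]))
  # identical groups: z = 0, p = 1
  same <- dunn_test(rep(c(5, 7), each = 4), rep(1:2, 4))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  # adjustment = none leaves p untouched; bonferroni/holm never decrease it
  set.seed(46)
  v <- rnorm(30); g <- rep(1:3, 10)
  none <- dunn_test(v, g, adjustment = "none")
  expect_identical(none$p, none$p_adj)
  bonf <- dunn_test(v, g, adjustment = "bonferroni")
  expect_true(all(bonf$p_adj >= bonf$p))
})

test_that("letter display satisfies share-a-letter iff not-significant, exhaustively to 4 levels", {
  for (k in 2:4) {
    lev <- as.character(seq_len(k))
    pairs <- t(combn(lev, 2))
    n_pairs <- nrow(pairs)
    for (mask in 0:(2^n_pairs - 1)) {
      sig <- as.logical(bitwAnd(mask, 2^(seq_len(n_pairs) - 1)))
      pw <- data.frame(level_1 = pairs[, 1], level_2 = pairs[, 2],
                       significant = sig)
      letts <- letter_display(pw)
      for (pr in seq_len(n_pairs)) {
        share <- length(intersect(strsplit(letts[pairs[pr, 1]], "")[[1]],
                                  strsplit(letts[pairs[pr, 2]], "")[[1]])) > 0
        expect_identical(share, !sig[pr],
                         info = sprintf("k=%d mask=%d pair=%s-%s", k, mask,
                                        pairs[pr, 1], pairs[pr, 2]))
      }
      expect_true(all(nchar(letts) >= 1))
    }
  }
})

test_that("letter display handles the canonical patterns and rejects missing pairs", {
  full <- data.frame(level_1 = c("1", "1", "2"), level_2 = c("2", "3", "3"),
                     significant = TRUE)
  expect_equal(unname(letter_display(full)), c("a", "b", "c"))
  none <- transform(full, significant = FALSE)
  expect_equal(unname(letter_display(none)), c("a", "a", "a"))
  chain <- data.frame(level_1 = c("1", "1", "2"), level_2 = c("2", "3", "3"),
                      significant = c(FALSE, TRUE, FALSE))
  expect_equal(unname(letter_display(chain)), c("a", "ab", "b"))
  expect_error(letter_display(full[-2, ]), "missing pairwise")
})

test_that("stratified analysis separates salinities, prunes no-growth levels and labels letters", {
  # build a rate table with structure: pH 1 never grows; only pH 7/25C and
  # pH 7/37C cells grow, with a temperature effect
  set.seed(47)
  grid <- expand.grid(organism = "f", salinity = c(0, 30), pH = c(1, 5, 7),
                      temperature = c(25, 37), replicate = 1:6)
  grid$growth_flag <- grid$pH > 1
  grid$rate <- ifelse(grid$growth_flag,
                      0.05 + 0.03 * (grid$temperature == 37) +
                        0.01 * (grid$pH == 7) + rnorm(nrow(grid), 0, 0.004),
                      0)
  st <- growth_rate_stats(grid)
  expect_s3_class(st, "growth_stats")
  expect_equal(length(st), 2)  # one stratum per salinity
  s0 <- st[["f @ 0"]]
  expect_equal(s0$dropped_levels$pH, 1)
  expect_equal(s0$effects$effect, c("pH", "temperature", "pH:temperature"))
  # strong temperature effect must be detected
  expect_lt(s0$effects$p[s0$effects$effect == "temperature"], 0.001)
  # post hoc letters exist for each retained conditioning level
  expect_true("pH=7" %in% names(s0$posthoc))
  letts <- s0$posthoc[["pH=7"]]$letters
  expect_equal(sort(names(letts)), c("25", "37"))
  expect_false(letts[["25"]] == letts[["37"]])  # separated temperatures
  tabs <- tabulate_growth_stats(st)
  expect_true(all(c("effects", "pairwise", "letters") %in% names(tabs)))
  expect_true(nrow(tabs$letters) > 0)
})

test_that("degenerate strata skip the two-way ANOVA but keep the one-way chain", {
  set.seed(48)
  grid <- expand.grid(organism = "f", salinity = 0, pH = c(1, 7),
                      temperature = c(25, 37), replicate = 1:5)
  grid$growth_flag <- grid$pH > 1
  grid$rate <- ifelse(grid$growth_flag,
                      0.05 + 0.02 * (grid$temperature == 37) +
                        rnorm(nrow(grid), 0, 0.003), 0)
  st <- growth_rate_stats(grid)
  s <- st[[1]]
  expect_null(s$effects)
  expect_match(s$notes, "degenerate")
  expect_true("pH=7" %in% names(s$posthoc))
})
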