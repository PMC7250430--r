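#' Shapiro-Wilk normality check
#'
#' Thin wrapper around \code{stats::shapiro.test} with the pipeline's
#' precondition checks, used to screen replicate-level growth rates before
#' deciding on rank-based methods.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return List with \code{statistic} (W) and \code{p}.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("insufficient data: Shapiro-Wilk needs n >= 3, got ", n)
  if (n > 5000) stop("Shapiro-Wilk supports n <= 5000, got ", n)
  t <- stats::shapiro.test(values)
  list(statistic = unname(t$statistic), p = unname(t$p.value))
}

#' Brown-Forsythe test of variance homogeneity
#'
#' Levene-type test on absolute deviations from group medians (the
#' median-centred variant is the Brown-Forsythe test), via
#' \code{car::leveneTest}. When every observation is identical the statistic
#' is degenerate; that case is reported as a non-rejection (p = 1) with a
#' warning rather than an error.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length as \code{values}; >= 2 groups,
#'   each with n >= 2.
#' @return List with \code{statistic} (F), \code{df} (numerator,
#'   denominator) and \code{p}.
#' @export
brown_forsythe <- function(values, groups) {
  if (length(values) != length(groups)) stop("'values' and 'groups' lengths differ")
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2)) stop("every group needs n >= 2")
  dev <- abs(values - stats::ave(values, g, FUN = stats::median))
  if (all(dev == 0)) {
    warning("all observations identical within groups; Brown-Forsythe statistic degenerate, reporting non-rejection")
    return(list(statistic = NA_real_, df = c(nlevels(g) - 1, length(values) - nlevels(g)),
                p = 1))
  }
  t <- car::leveneTest(values, g, center = stats::median)
  list(statistic = t[1, "F value"], df = c(t[1, "Df"], t[2, "Df"]),
       p = t[1, "Pr(>F)"])
}

#' Kruskal-Wallis rank test
#'
#' The nonparametric one-way ANOVA on ranks with tie correction, used per
#' level of the conditioning factor once the two-way interaction is
#' established. Wraps \code{stats::kruskal.test}; a fully tied sample (H
#' undefined, 0/0) is reported as H = 0, p = 1.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length; >= 2 groups, total n >= 3, no
#'   empty group.
#' @return List with \code{statistic} (H), \code{df} and \code{p}.
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(values) != length(groups)) stop("'values' and 'groups' lengths differ")
  g <- if (is.factor(groups)) groups else factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) == 0)) stop("empty group")
  if (length(values) < 3) stop("total n must be >= 3")
  if (length(unique(values)) == 1) {
    return(list(statistic = 0, df = nlevels(g) - 1, p = 1))
  }
  t <- stats::kruskal.test(values, g)
  list(statistic = unname(t$statistic), df = unname(t$parameter),
       p = unname(t$p.value))
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Rank-based pairwise z tests following a Kruskal-Wallis test. For groups i
#' and j with mean ranks \eqn{\bar R_i, \bar R_j} over the pooled sample of
#' size N,
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) /
#'   \sqrt{\Big(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12 (N-1)}\Big)
#'         \Big(\frac{1}{n_i} + \frac{1}{n_j}\Big)}}
#' with the tie term summed over tie groups of size t. P-values are
#' two-sided normal; the multiplicity adjustment is configurable
#' (\code{"none"} by default, \code{"bonferroni"} or \code{"holm"}
#' otherwise).
#'
#' @param values numeric response vector.
#' @param groups group labels; >= 2 non-empty groups.
#' @param alpha significance level for the per-pair flags.
#' @param adjustment one of \code{"none"}, \code{"bonferroni"},
#'   \code{"holm"}.
#' @return Data frame with columns level_1, level_2, z, p, p_adj,
#'   significant. Levels are compared in sorted order.
#' @export
dunn_test <- function(values, groups, alpha = 0.05,
                      adjustment = c("none", "bonferroni", "holm")) {
  adjustment <- match.arg(adjustment)
  if (length(values) != length(groups)) stop("'values' and 'groups' lengths differ")
  g <- if (is.factor(groups)) groups else factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) == 0)) stop("empty group")
  N <- length(values)
  r <- rank(values, ties.method = "average")
  mean_rank <- tapply(r, g, mean)
  n <- table(g)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term

  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(var_base * (1 / n[[i]] + 1 / n[[j]]))
    z <- if (se > 0) (mean_rank[[i]] - mean_rank[[j]]) / se else 0
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(level_1 = pairs[1, ], level_2 = pairs[2, ],
                    z = res["z", ], p = pmin(res["p", ], 1),
                    stringsAsFactors = FALSE)
  out$p_adj <- stats::p.adjust(out$p, method = adjustment)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Compact letter display from pairwise comparisons
#'
#' Assigns letters to factor levels so that two levels share at least one
#' letter if and only if they are not significantly different, by the
#' insert-and-absorb algorithm: start from one group holding all levels;
#' for every significant pair split each group containing both into two
#' copies, one without each member; absorb groups that became subsets of
#' others; finally label the surviving groups a, b, c, ... in order of their
#' first (sorted) member.
#'
#' @param pairwise data frame from \code{\link{dunn_test}} (needs columns
#'   level_1, level_2, significant) covering every pair of levels.
#' @param levels optional character vector fixing the level order; defaults
#'   to the sorted union of the pair columns.
#' @return Named character vector: per level, its letters collapsed into a
#'   string.
#' @examples
#' pw <- data.frame(level_1 = c("15", "15", "25"),
#'                  level_2 = c("25", "37", "37"),
#'                  significant = c(FALSE, TRUE, FALSE))
#' letter_display(pw)  # "ab" in the middle, "a" and "b" at the ends
#' @export
letter_display <- function(pairwise, levels = NULL) {
  need <- c("level_1", "level_2", "significant")
  if (!all(need %in% names(pairwise))) stop("'pairwise' needs columns ",
                                            paste(need, collapse = ", "))
  lev <- if (is.null(levels)) sort(unique(c(pairwise$level_1, pairwise$level_2)))
         else as.character(levels)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "\r")
  seen <- key(as.character(pairwise$level_1), as.character(pairwise$level_2))
  all_pairs <- utils::combn(lev, 2)
  want <- key(all_pairs[1, ], all_pairs[2, ])
  if (!all(want %in% seen)) {
    miss <- all_pairs[, which(!(want %in% seen))[1]]
    stop("missing pairwise result for levels ", miss[1], " vs ", miss[2])
  }
  sig <- pairwise[pairwise$significant, c("level_1", "level_2")]

  groups <- list(lev)
  for (idx in seq_len(nrow(sig))) {
    i <- as.character(sig$level_1[idx]); j <- as.character(sig$level_2[idx])
    new_groups <- list()
    for (grp in groups) {
      if (i %in% grp && j %in% grp) {
        new_groups <- c(new_groups, list(setdiff(grp, i)), list(setdiff(grp, j)))
      } else {
        new_groups <- c(new_groups, list(grp))
      }
    }
    # absorb: drop any group fully contained in another
    keep <- rep(TRUE, length(new_groups))
    for (g1 in seq_along(new_groups)) {
      for (g2 in seq_along(new_groups)) {
        if (g1 != g2 && keep[g1] && keep[g2] &&
            all(new_groups[[g1]] %in% new_groups[[g2]]) &&
            (length(new_groups[[g1]]) < length(new_groups[[g2]]) || g1 > g2)) {
          keep[g1] <- FALSE
        }
      }
    }
    groups <- new_groups[keep]
  }
  groups <- groups[order(vapply(groups, function(g) match(g[1], lev), 1L))]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- stats::setNames(rep("", length(lev)), lev)
  for (gi in seq_along(groups)) {
    for (l in groups[[gi]]) out[l] <- paste0(out[l], letters_pool[gi])
  }
  out
}
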