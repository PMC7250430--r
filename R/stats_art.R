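#' Aligned rank transform for a two-factor layout
#'
#' Prepares a response for nonparametric factorial ANOVA by aligning and
#' ranking it once per effect. For each effect E in \{A, B, A:B\} the aligned
#' response is the residual from the full cell-means model plus the estimated
#' contribution of E alone: main effects are estimated from marginal means
#' minus the grand mean, the interaction from cell mean minus both marginal
#' means plus the grand mean. Aligned values are then mid-ranked (average
#' ranks for ties). By construction, re-estimating any non-focal effect from
#' an aligned column gives zero, which \code{art_anova} asserts before
#' testing.
#'
#' @param data data frame containing the response and both factors; every
#'   cell of the A x B cross must be non-empty.
#' @param response name of the response column.
#' @param factor_a,factor_b names of the two factor columns.
#' @return An object of class \code{art_table}: the input data plus, per
#'   effect, \code{aligned_<effect>} and \code{rank_<effect>} columns.
#' @examples
#' tab <- simulate_rate_table(c(0, 1), c(0, 0), n_per_cell = 4, seed = 7)
#' art <- art_transform(tab, "y", "A", "B")
#' art_anova(art)
#' @export
art_transform <- function(data, response, factor_a, factor_b) {
  for (col in c(response, factor_a, factor_b)) {
    if (!col %in% names(data)) stop("column '", col, "' not found")
  }
  y <- data[[response]]
  if (!is.numeric(y) || anyNA(y)) stop("response must be numeric with no missing values")
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  if (nlevels(A) < 2) stop("factor '", factor_a, "' has fewer than 2 levels")
  if (nlevels(B) < 2) stop("factor '", factor_b, "' has fewer than 2 levels")
  counts <- table(A, B)
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: ", factor_a, "=", levels(A)[empty[1]], ", ",
         factor_b, "=", levels(B)[empty[2]])
  }

  grand <- mean(y)
  cell_mean <- tapply(y, list(A, B), mean)
  a_mean <- tapply(y, A, mean)
  b_mean <- tapply(y, B, mean)
  resid <- y - cell_mean[cbind(A, B)]

  eff <- list(
    A = a_mean[A] - grand,
    B = b_mean[B] - grand,
    AB = cell_mean[cbind(A, B)] - a_mean[A] - b_mean[B] + grand
  )
  out <- data
  for (e in names(eff)) {
    aligned <- resid + eff[[e]]
    out[[paste0("aligned_", e)]] <- as.numeric(aligned)
    out[[paste0("rank_", e)]] <- rank(aligned, ties.method = "average")
  }
  structure(out, class = c("art_table", "data.frame"),
            art = list(response = response, factor_a = factor_a,
                       factor_b = factor_b))
}

# estimated contribution of every non-focal effect in an aligned column;
# must vanish (to numerical precision) for a correct alignment
art_alignment_error <- function(art) {
  meta <- attr(art, "art")
  A <- factor(art[[meta$factor_a]])
  B <- factor(art[[meta$factor_b]])
  err <- c(A = 0, B = 0, AB = 0)
  for (e in names(err)) {
    v <- art[[paste0("aligned_", e)]]
    grand <- mean(v)
    am <- tapply(v, A, mean) - grand
    bm <- tapply(v, B, mean) - grand
    ab <- tapply(v, list(A, B), mean)
    abm <- ab - outer(tapply(v, A, mean), tapply(v, B, mean), `+`) + grand
    other <- switch(e,
                    A = c(bm, abm),
                    B = c(am, abm),
                    AB = c(am, bm))
    err[e] <- max(abs(other))
  }
  err
}

#' Two-way ANOVA on aligned ranks
#'
#' Runs a fixed-effects two-way ANOVA on each effect's rank column of an
#' \code{\link{art_transform}} table and reports only the focal effect's F
#' statistic and p-value from each fit — the standard way interaction and
#' main effects are tested after an aligned rank transform. The alignment
#' identity (all non-focal effect estimates zero before ranking) is checked
#' and a violation beyond \code{tol} is an error.
#'
#' @param art an \code{art_table}.
#' @param tol tolerance for the alignment identity check.
#' @return Data frame with columns effect, F, df1, df2, p.
#' @export
art_anova <- function(art, tol = 1e-9) {
  if (!inherits(art, "art_table")) stop("'art' must come from art_transform()")
  err <- art_alignment_error(art)
  if (any(err > tol)) stop("alignment identity violated (max residual effect ",
                           format(max(err)), ")")
  meta <- attr(art, "art")
  A <- factor(art[[meta$factor_a]])
  B <- factor(art[[meta$factor_b]])
  pick <- c(A = meta$factor_a, B = meta$factor_b,
            AB = paste(meta$factor_a, meta$factor_b, sep = ":"))
  res <- lapply(names(pick), function(e) {
    r <- art[[paste0("rank_", e)]]
    tab <- stats::anova(stats::lm(r ~ A * B))
    row <- switch(e, A = "A", B = "B", AB = "A:B")
    df2 <- tab["Residuals", "Df"]
    if (df2 < 1) stop("insufficient residual degrees of freedom")
    data.frame(effect = pick[[e]], F = tab[row, "F value"],
               df1 = tab[row, "Df"], df2 = df2,
               p = tab[row, "Pr(>F)"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
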