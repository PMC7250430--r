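#' Factorial statistics on a growth-rate table
#'
#' Runs the full statistical chain on replicate-level normalized growth
#' rates, separately for every (organism, salinity) stratum — freshwater and
#' seawater data are never pooled:
#' \enumerate{
#'   \item screening: Shapiro-Wilk normality and Brown-Forsythe variance
#'     homogeneity on the stratum's rates (reported, not gating);
#'   \item factor-level pruning: pH or temperature levels with no growing
#'     well anywhere in the stratum (e.g. pH 1, or 45 degrees C for a
#'     non-thermotolerant organism) are removed before the factorial
#'     analysis; remaining no-growth replicates stay in as rate 0 so the
#'     cross stays complete;
#'   \item aligned rank transform and two-way ANOVA for the pH,
#'     temperature and interaction effects (skipped with a notice when
#'     pruning leaves a factor with one level);
#'   \item per-level post hoc: at each retained pH, a Kruskal-Wallis test
#'     across temperatures followed by Dunn's pairwise comparisons and a
#'     compact letter display, and symmetrically at each retained
#'     temperature across pH levels.
#' }
#'
#' @param rates growth-rate table (columns organism, salinity, pH,
#'   temperature, replicate, rate, growth_flag), e.g. from
#'   \code{\link{fit_plate}}.
#' @param alpha significance level for Dunn flags and letters.
#' @param adjustment Dunn multiplicity adjustment: \code{"none"} (default),
#'   \code{"bonferroni"} or \code{"holm"}.
#' @return An object of class \code{growth_stats}: a list of strata, each
#'   with \code{organism}, \code{salinity}, \code{screen}, \code{effects}
#'   (data frame or NULL), \code{posthoc} (list of per-level results with
#'   pairwise tables and letters), \code{dropped_levels} and \code{notes}.
#' @export
growth_rate_stats <- function(rates, alpha = 0.05,
                              adjustment = c("none", "bonferroni", "holm")) {
  adjustment <- match.arg(adjustment)
  need <- c("organism", "salinity", "pH", "temperature", "replicate",
            "rate", "growth_flag")
  if (!all(need %in% names(rates))) stop("rate table needs columns ",
                                         paste(need, collapse = ", "))
  strata <- split(rates, list(rates$organism, rates$salinity), drop = TRUE)
  out <- lapply(strata, function(s)
    analyze_stratum(s, alpha = alpha, adjustment = adjustment))
  names(out) <- vapply(out, function(s) paste(s$organism, s$salinity, sep = " @ "),
                       "")
  out <- out[order(names(out))]
  structure(out, class = "growth_stats", alpha = alpha,
            adjustment = adjustment)
}

analyze_stratum <- function(s, alpha, adjustment) {
  notes <- character()
  res <- list(organism = s$organism[1], salinity = s$salinity[1])

  res$screen <- list(
    shapiro = tryCatch(shapiro_wilk(s$rate), error = function(e) NULL),
    brown_forsythe = tryCatch(
      suppressWarnings(brown_forsythe(s$rate, interaction(s$pH, s$temperature))),
      error = function(e) NULL)
  )

  # prune factor levels with no growth anywhere in the stratum
  grow_ph <- tapply(s$growth_flag, s$pH, any)
  grow_tt <- tapply(s$growth_flag, s$temperature, any)
  keep_ph <- as.numeric(names(grow_ph)[grow_ph])
  keep_tt <- as.numeric(names(grow_tt)[grow_tt])
  res$dropped_levels <- list(
    pH = as.numeric(names(grow_ph)[!grow_ph]),
    temperature = as.numeric(names(grow_tt)[!grow_tt])
  )
  su <- s[s$pH %in% keep_ph & s$temperature %in% keep_tt, ]

  res$effects <- NULL
  res$posthoc <- list()
  if (nrow(su) == 0) {
    res$notes <- "no growth anywhere in stratum; analysis skipped"
    return(res)
  }
  if (length(keep_ph) >= 2 && length(keep_tt) >= 2) {
    art <- art_transform(su, "rate", "pH", "temperature")
    res$effects <- art_anova(art)
  } else {
    notes <- c(notes, "degenerate stratum: a factor has one level after pruning; two-way ANOVA skipped")
  }

  posthoc <- list()
  if (length(keep_tt) >= 2) {
    for (p in keep_ph) {
      sub <- su[su$pH == p, ]
      posthoc[[paste0("pH=", p)]] <- posthoc_one(sub$rate, sub$temperature,
                                                 alpha, adjustment)
    }
  }
  if (length(keep_ph) >= 2) {
    for (tt in keep_tt) {
      sub <- su[su$temperature == tt, ]
      posthoc[[paste0("temperature=", tt)]] <- posthoc_one(sub$rate, sub$pH,
                                                           alpha, adjustment)
    }
  }
  res$posthoc <- posthoc
  res$notes <- if (length(notes)) notes else character()
  res
}

posthoc_one <- function(values, groups, alpha, adjustment) {
  kw <- kruskal_wallis(values, groups)
  pw <- dunn_test(values, groups, alpha = alpha, adjustment = adjustment)
  list(kruskal = kw, pairwise = pw, letters = letter_display(pw))
}

#' @export
print.growth_stats <- function(x, ...) {
  cat("Growth-rate factorial statistics:", length(x), "stratum/strata\n")
  for (nm in names(x)) {
    s <- x[[nm]]
    cat("\n--", nm, "--\n")
    if (!is.null(s$effects)) {
      print(transform(s$effects, F = round(F, 3), p = signif(p, 3)))
    } else {
      cat("  two-way ANOVA skipped\n")
    }
    if (length(s$notes)) cat("  note:", s$notes, "\n")
  }
  invisible(x)
}

#' Flatten growth_stats into exportable tables
#'
#' @param stats a \code{growth_stats} object.
#' @return List of three data frames: \code{effects} (stratum, effect, F,
#'   df1, df2, p), \code{pairwise} (stratum, conditioning level, pair, z, p,
#'   p_adj, significant) and \code{letters} (stratum, conditioning level,
#'   level, letters).
#' @export
tabulate_growth_stats <- function(stats) {
  stopifnot(inherits(stats, "growth_stats"))
  eff <- list(); pw <- list(); lt <- list()
  for (nm in names(stats)) {
    s <- stats[[nm]]
    if (!is.null(s$effects)) eff[[nm]] <- data.frame(stratum = nm, s$effects)
    for (lv in names(s$posthoc)) {
      ph <- s$posthoc[[lv]]
      pw[[paste(nm, lv)]] <- data.frame(stratum = nm, within = lv, ph$pairwise)
      lt[[paste(nm, lv)]] <- data.frame(stratum = nm, within = lv,
                                        level = names(ph$letters),
                                        letters = unname(ph$letters))
    }
  }
  bind <- function(l, cols) if (length(l)) do.call(rbind, c(l, make.row.names = FALSE))
    else stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  list(effects = bind(eff, c("stratum", "effect", "F", "df1", "df2", "p")),
       pairwise = bind(pw, c("stratum", "within", "level_1", "level_2", "z",
                             "p", "p_adj", "significant")),
       letters = bind(lt, c("stratum", "within", "level", "letters")))
}
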