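#' Summarize growth occurrence per organism and condition
#'
#' Collapses a replicate-level growth-rate table into one organism's
#' response profile: per (salinity, pH, temperature) condition, a growth
#' flag (true when at least half of the replicates were called growing) and
#' the mean normalized growth rate over the growing replicates (0 when
#' none grew).
#'
#' @param rates growth-rate table with columns organism, salinity, pH,
#'   temperature, growth_flag and (optionally) rate. A table with one row
#'   per condition, e.g. a presence/absence fixture, works as a 1-replicate
#'   table.
#' @param organism organism label to summarize.
#' @return An object of class \code{response_profile}: data frame with
#'   columns salinity, pH, temperature, growth, mean_rate, plus the
#'   organism label as an attribute.
#' @export
response_profile <- function(rates, organism) {
  need <- c("organism", "salinity", "pH", "temperature", "growth_flag")
  if (!all(need %in% names(rates))) stop("rate table needs columns ",
                                         paste(need, collapse = ", "))
  sub <- rates[rates$organism == organism, ]
  if (nrow(sub) == 0) stop("organism '", organism, "' not found in rate table")
  if (!"rate" %in% names(sub)) sub$rate <- 0
  key <- interaction(sub$salinity, sub$pH, sub$temperature, drop = TRUE)
  rows <- lapply(split(sub, key), function(cell) {
    grow <- mean(cell$growth_flag) >= 0.5
    mr <- if (any(cell$growth_flag)) mean(cell$rate[cell$growth_flag]) else 0
    data.frame(salinity = cell$salinity[1], pH = cell$pH[1],
               temperature = cell$temperature[1], growth = grow,
               mean_rate = mr)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$salinity, out$pH, out$temperature), ]
  rownames(out) <- NULL
  structure(out, class = c("response_profile", "data.frame"),
            organism = organism)
}

#' Classification rules for environmental-response groups
#'
#' The three groups are operationalized as ordered clauses over a growth
#' presence/absence profile:
#' \enumerate{
#'   \item \strong{temperature_tolerant}: growth at the thermotolerance
#'     temperature (45 degrees C) under any salinity and pH. This clause
#'     dominates because growth at 45 degrees C alone defines the group.
#'   \item \strong{wide_range}: growth at 37 degrees C, growth at pH 3 under
#'     at least one (salinity, temperature), and growth in both salinities.
#'     By default growth at 37 degrees C is required in \emph{both}
#'     salinities: organisms whose warm growth appears only in seawater are
#'     salinity-dependent, not wide-range, and this distinction is what
#'     separates the two groups among the vent isolates.
#'   \item \strong{salinity_dependent_temperature_sensitive}: everything
#'     else.
#' }
#'
#' @param thermo_temp temperature whose growth defines thermotolerance
#'   (degrees C).
#' @param wide_temp warm temperature required for the wide-range group.
#' @param wide_ph acidic pH required for the wide-range group.
#' @param wide_temp_both_salinities require growth at \code{wide_temp} in
#'   both salinities (default) rather than in at least one.
#' @return List of rule settings for \code{\link{classify_response}}.
#' @export
response_rules <- function(thermo_temp = 45, wide_temp = 37, wide_ph = 3,
                           wide_temp_both_salinities = TRUE) {
  list(thermo_temp = thermo_temp, wide_temp = wide_temp, wide_ph = wide_ph,
       wide_temp_both_salinities = wide_temp_both_salinities)
}

#' Assign an organism to an environmental-response group
#'
#' Applies the ordered clauses of \code{\link{response_rules}} to a growth
#' occurrence profile. Every profile receives exactly one of
#' \code{"temperature_tolerant"}, \code{"wide_range"},
#' \code{"salinity_dependent_temperature_sensitive"}.
#'
#' @param profile a \code{\link{response_profile}}.
#' @param rules rule settings from \code{\link{response_rules}}.
#' @return Character group label with attribute \code{"clause"} naming the
#'   clause that fired.
#' @export
classify_response <- function(profile, rules = response_rules()) {
  if (!inherits(profile, "response_profile")) stop("'profile' must come from response_profile()")
  sal <- sort(unique(profile$salinity))
  need <- c(rules$thermo_temp, rules$wide_temp)
  if (!all(need %in% profile$temperature))
    stop("profile does not cover required temperature level(s): ",
         paste(setdiff(need, profile$temperature), collapse = ", "))
  if (!rules$wide_ph %in% profile$pH)
    stop("profile does not cover pH ", rules$wide_ph)
  g <- profile[profile$growth, ]

  if (any(g$temperature >= rules$thermo_temp))
    return(structure("temperature_tolerant", clause = "growth_at_thermo_temp"))

  warm_sal <- unique(g$salinity[g$temperature == rules$wide_temp])
  warm_ok <- if (rules$wide_temp_both_salinities) all(sal %in% warm_sal)
             else length(warm_sal) > 0
  acid_ok <- any(g$pH == rules$wide_ph)
  both_sal_ok <- all(sal %in% unique(g$salinity))
  if (warm_ok && acid_ok && both_sal_ok)
    return(structure("wide_range", clause = "warm_acid_both_salinities"))

  structure("salinity_dependent_temperature_sensitive", clause = "fallback")
}

#' Count organisms per response group
#'
#' @param labels character vector of group labels from
#'   \code{\link{classify_response}} (one per organism).
#' @return Named integer vector over the three groups; counts sum to the
#'   number of organisms.
#' @export
group_counts <- function(labels) {
  groups <- c("wide_range", "salinity_dependent_temperature_sensitive",
              "temperature_tolerant")
  bad <- setdiff(unique(labels), groups)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  out <- stats::setNames(integer(length(groups)), groups)
  tab <- table(factor(unlist(labels), levels = groups))
  out[names(tab)] <- as.integer(tab)
  out
}

#' Classify every organism in a growth-rate table
#'
#' @param rates growth-rate table (see \code{\link{response_profile}}).
#' @param rules rule settings from \code{\link{response_rules}}.
#' @return Data frame with columns organism, group, clause.
#' @export
classify_rate_table <- function(rates, rules = response_rules()) {
  orgs <- sort(unique(rates$organism))
  rows <- lapply(orgs, function(o) {
    lbl <- classify_response(response_profile(rates, o), rules)
    data.frame(organism = o, group = as.character(lbl),
               clause = attr(lbl, "clause"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Growth occurrence of ten hydrothermal-vent fungal isolates
#'
#' Loads the packaged presence/absence table recording, for each of ten
#' fungal isolates from the Kueishan Island shallow hydrothermal vent field,
#' whether mycelial growth occurred at each tested combination of salinity
#' (0 and 30 permille), pH (1, 3, 5, 7, 9) and temperature (15, 25, 37, 45
#' degrees C). No isolate grows at pH 1; a single isolate (an
#' \emph{Aspergillus terreus} strain) grows at 45 degrees C. The table is an
#' encoding of reported growth ranges, not raw instrument output, and is the
#' reference input for the response-group classifier.
#'
#' @return Data frame with columns organism, salinity, pH, temperature,
#'   growth_flag.
#' @examples
#' prof <- vent_fungi_growth()
#' cls <- classify_rate_table(prof)
#' group_counts(cls$group)
#' @export
vent_fungi_growth <- function() {
  path <- system.file("extdata", "vent_fungi_growth.csv",
                      package = "ventgrowth", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$growth_flag <- as.logical(tab$growth_flag)
  tab
}
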