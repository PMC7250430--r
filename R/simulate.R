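#' Define a factorial microplate design
#'
#' Enumerates the wells of a salinity x pH x temperature factorial plate
#' assay. Each organism receives \code{replicates} inoculated wells per
#' treatment; optionally one set of uninoculated control wells per treatment
#' (shared across organisms) is added for blank subtraction. The default
#' levels reproduce a 2-salinity x 5-pH x 4-temperature x 8-replicate layout,
#' i.e. 320 inoculated wells per organism.
#'
#' @param salinities salinity levels (permille); non-empty numeric.
#' @param phs pH levels; non-empty numeric.
#' @param temperatures temperatures (degrees C); non-empty numeric.
#' @param replicates inoculated wells per treatment per organism (>= 1).
#' @param organisms character vector of organism labels.
#' @param days number of daily readings; the time grid is day 0 to
#'   \code{days - 1} (>= 2).
#' @param include_controls add one set of \code{replicates} uninoculated
#'   control wells per treatment?
#' @return An object of class \code{plate_design}: a list with the level
#'   vectors and a \code{wells} data frame (well_id, organism, salinity, pH,
#'   temperature, replicate, role).
#' @examples
#' d <- plate_design(organisms = "Aspergillus terreus")
#' n_wells(d)  # 320 inoculated wells
#' @export
plate_design <- function(salinities = c(0, 30),
                         phs = c(1, 3, 5, 7, 9),
                         temperatures = c(15, 25, 37, 45),
                         replicates = 8,
                         organisms = "organism_1",
                         days = 30,
                         include_controls = TRUE) {
  for (nm in c("salinities", "phs", "temperatures")) {
    v <- get(nm)
    if (length(v) == 0 || !is.numeric(v)) stop("invalid design: '", nm, "' must be non-empty numeric")
    if (anyDuplicated(v)) stop("invalid design: duplicated levels in '", nm, "'")
  }
  if (length(organisms) == 0) stop("invalid design: at least one organism required")
  if (!is.numeric(replicates) || replicates < 1 || replicates != round(replicates))
    stop("invalid design: 'replicates' must be an integer >= 1")
  if (!is.numeric(days) || days < 2) stop("invalid design: 'days' must be >= 2")

  trt <- expand.grid(salinity = salinities, pH = phs, temperature = temperatures,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  inoc <- merge(expand.grid(organism = organisms, replicate = seq_len(replicates),
                            stringsAsFactors = FALSE), trt)
  inoc <- inoc[, c("organism", "salinity", "pH", "temperature", "replicate")]
  inoc$role <- "inoculated"
  wells <- inoc
  if (include_controls) {
    ctrl <- merge(data.frame(organism = "none", replicate = seq_len(replicates),
                             stringsAsFactors = FALSE), trt)
    ctrl <- ctrl[, c("organism", "salinity", "pH", "temperature", "replicate")]
    ctrl$role <- "control"
    wells <- rbind(wells, ctrl)
  }
  wells <- wells[order(wells$role, wells$organism, wells$salinity, wells$pH,
                       wells$temperature, wells$replicate), ]
  wells$well_id <- sprintf("%s|s%g|p%g|t%g|r%d|%s", wells$organism,
                           wells$salinity, wells$pH, wells$temperature,
                           wells$replicate, substr(wells$role, 1, 1))
  rownames(wells) <- NULL
  structure(list(salinities = salinities, phs = phs,
                 temperatures = temperatures, replicates = replicates,
                 organisms = organisms, days = days,
                 include_controls = include_controls,
                 wells = wells[, c("well_id", "organism", "salinity", "pH",
                                   "temperature", "replicate", "role")]),
            class = "plate_design")
}

#' Count inoculated wells per organism in a design
#' @param design a \code{plate_design}.
#' @return Integer: inoculated wells per organism
#'   (levels product times replicates).
#' @export
n_wells <- function(design) {
  stopifnot(inherits(design, "plate_design"))
  as.integer(length(design$salinities) * length(design$phs) *
               length(design$temperatures) * design$replicates)
}

#' @export
print.plate_design <- function(x, ...) {
  cat("Plate design:", length(x$salinities), "salinities x", length(x$phs),
      "pHs x", length(x$temperatures), "temperatures x", x$replicates,
      "replicates\n")
  cat(" ", n_wells(x), "inoculated wells per organism;",
      length(x$organisms), "organism(s);", x$days, "daily readings\n")
  if (x$include_controls) cat("  one control set per treatment\n")
  invisible(x)
}

#' Ground truth for a simulated plate
#'
#' Pairs a design with per-cell Richards parameters (or a no-growth marker),
#' a measurement-noise level and a control-well baseline. \code{params} must
#' cover every (organism, salinity, pH, temperature) cell of the design
#' exactly once; \code{growth = FALSE} rows mark no-growth cells whose
#' parameter columns are ignored.
#'
#' @param design a \code{plate_design}.
#' @param params data frame with columns organism, salinity, pH, temperature,
#'   growth, a, k, d, xc.
#' @param noise_sd standard deviation of additive Gaussian OD noise
#'   (absorbance units, >= 0).
#' @param baseline uninoculated-well OD level (absorbance units, >= 0).
#' @param seed master integer seed; every well draws its noise from a
#'   deterministic substream keyed by its well id, so subsetting the design
#'   leaves per-well noise unchanged.
#' @return An object of class \code{ground_truth}.
#' @seealso \code{\link{default_ground_truth}} for a ready-made truth table.
#' @export
ground_truth <- function(design, params, noise_sd = 0.01, baseline = 0.05,
                         seed = 1L) {
  stopifnot(inherits(design, "plate_design"))
  need <- c("organism", "salinity", "pH", "temperature", "growth", "a", "k", "d", "xc")
  if (!all(need %in% names(params))) stop("'params' missing columns: ",
                                          paste(setdiff(need, names(params)), collapse = ", "))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (baseline < 0) stop("'baseline' must be >= 0")
  cells <- unique(design$wells[design$wells$role == "inoculated",
                               c("organism", "salinity", "pH", "temperature")])
  key <- function(df) paste(df$organism, df$salinity, df$pH, df$temperature, sep = "\r")
  pk <- key(params)
  if (anyDuplicated(pk)) stop("duplicate cells in 'params'")
  missing <- setdiff(key(cells), pk)
  if (length(missing))
    stop("ground truth does not cover ", length(missing), " design cell(s), e.g. ",
         gsub("\r", "/", missing[1]))
  for (i in which(params$growth)) {
    check_richards_params(params$a[i], params$k[i], params$d[i], params$xc[i])
  }
  structure(list(params = params, noise_sd = noise_sd, baseline = baseline,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Default ground truth emulating the vent-fungi assay structure
#'
#' Builds a plausible truth table for a design: no growth at pH 1 for any
#' organism; at 45 degrees C only the first organism grows; elsewhere growth
#' with a peak rate constant at 25 degrees C falling off towards the
#' temperature extremes and mildly reduced at the pH extremes. Asymptotes
#' sit near 0.8 OD and inflection times near day 10-14, the scale seen in
#' month-long microplate fungal growth assays.
#'
#' @inheritParams ground_truth
#' @param thermotolerant_organism organism label allowed to grow at 45
#'   degrees C (default: the design's first organism).
#' @return A \code{ground_truth} object.
#' @export
default_ground_truth <- function(design, noise_sd = 0.01, baseline = 0.05,
                                 seed = 1L,
                                 thermotolerant_organism = design$organisms[1]) {
  cells <- unique(design$wells[design$wells$role == "inoculated",
                               c("organism", "salinity", "pH", "temperature")])
  temp_k <- function(tt) exp(-((tt - 25) / 14)^2)          # peak at 25 C
  ph_k <- function(p) 0.7 + 0.3 * exp(-((p - 6) / 4)^2)    # mild pH optimum
  grows <- cells$pH > 1 &
    (cells$temperature < 45 | cells$organism == thermotolerant_organism)
  params <- data.frame(
    cells,
    growth = grows,
    a = 0.8 - 0.004 * abs(cells$temperature - 25),
    k = pmax(0.6 * temp_k(cells$temperature) * ph_k(cells$pH), 0.08),
    d = 3,
    xc = 10 + 0.1 * abs(cells$temperature - 25),
    stringsAsFactors = FALSE
  )
  ground_truth(design, params, noise_sd = noise_sd, baseline = baseline,
               seed = seed)
}

# Deterministic per-well seed: polynomial hash of the well id folded with the
# master seed, kept below 2^31 so set.seed() accepts it.
well_seed <- function(master, well_id) {
  h <- 0
  for (cp in utf8ToInt(well_id)) h <- (h * 31 + cp) %% 2147483647
  as.integer((as.numeric(master) + h) %% 2147483647)
}

#' Simulate plate-reader OD time series
#'
#' Generates a long-format table of daily OD630 readings for every well of a
#' design. Growth wells follow \code{baseline + richards(day) + noise};
#' no-growth and control wells are \code{baseline + noise}. Noise is additive
#' Gaussian truncated at zero (absorbance is non-negative). Each well's noise
#' comes from its own seeded substream, so output is bit-for-bit reproducible
#' and independent of which other wells are simulated.
#'
#' @param design a \code{plate_design}.
#' @param truth a \code{ground_truth} covering the design.
#' @return Data frame with columns well_id, organism, salinity, pH,
#'   temperature, replicate, role, day, od630.
#' @examples
#' d <- plate_design(salinities = 0, phs = 7, temperatures = 25,
#'                   replicates = 2, organisms = "demo", days = 10)
#' head(simulate_plate(d, default_ground_truth(d, seed = 42)))
#' @export
simulate_plate <- function(design, truth) {
  stopifnot(inherits(design, "plate_design"), inherits(truth, "ground_truth"))
  days <- seq.int(0, design$days - 1)
  wells <- design$wells
  pk <- paste(truth$params$organism, truth$params$salinity, truth$params$pH,
              truth$params$temperature, sep = "\r")
  idx <- match(paste(wells$organism, wells$salinity, wells$pH,
                     wells$temperature, sep = "\r"), pk)
  if (any(is.na(idx) & wells$role == "inoculated"))
    stop("ground truth missing a design cell")

  per_well <- lapply(seq_len(nrow(wells)), function(i) {
    w <- wells[i, ]
    mu <- rep(truth$baseline, length(days))
    if (w$role == "inoculated") {
      p <- truth$params[idx[i], ]
      if (p$growth) mu <- mu + richards(days, p$a, p$k, p$d, p$xc)
    }
    if (truth$noise_sd > 0) {
      set.seed(well_seed(truth$seed, w$well_id))
      mu <- pmax(mu + stats::rnorm(length(days), 0, truth$noise_sd), 0)
    }
    data.frame(well_id = w$well_id, organism = w$organism,
               salinity = w$salinity, pH = w$pH, temperature = w$temperature,
               replicate = w$replicate, role = w$role, day = days, od630 = mu,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_well)
  rownames(out) <- NULL
  out
}

#' Simulate a balanced two-factor growth-rate table
#'
#' Builds a balanced long table with response = grand mean + main effects +
#' interaction + i.i.d. noise, for validating the factorial statistics
#' modules against known ground truth. Effects are supplied per level (main)
#' and per cell (interaction) and are centred internally so they are proper
#' contrasts.
#'
#' @param a_effects numeric vector of factor-A main effects (one per level,
#'   >= 2 levels).
#' @param b_effects numeric vector of factor-B main effects (>= 2 levels).
#' @param ab_effects interaction matrix (length(a) x length(b)), default all
#'   zero.
#' @param n_per_cell replicates per cell (>= 2).
#' @param sd noise standard deviation.
#' @param noise noise generator: \code{function(n)} returning n deviates;
#'   default Gaussian with sd \code{sd}.
#' @param mu grand mean.
#' @param seed integer seed.
#' @return Data frame (A, B, replicate, y) with attribute \code{"truth"}
#'   recording the centred effects.
#' @export
simulate_rate_table <- function(a_effects, b_effects, ab_effects = NULL,
                                n_per_cell = 8, sd = 1, noise = NULL,
                                mu = 0, seed = 1L) {
  if (length(a_effects) < 2 || length(b_effects) < 2)
    stop("both factors need at least 2 levels")
  if (n_per_cell < 2) stop("'n_per_cell' must be >= 2 (within-cell variance undefined otherwise)")
  I <- length(a_effects); J <- length(b_effects)
  if (is.null(ab_effects)) ab_effects <- matrix(0, I, J)
  if (!all(dim(ab_effects) == c(I, J))) stop("'ab_effects' must be a ", I, "x", J, " matrix")
  a_c <- a_effects - mean(a_effects)
  b_c <- b_effects - mean(b_effects)
  ab_c <- ab_effects - outer(rowMeans(ab_effects), colMeans(ab_effects), `+`) +
    mean(ab_effects)
  if (is.null(noise)) noise <- function(n) stats::rnorm(n, 0, sd)
  set.seed(as.integer(seed))
  grid <- expand.grid(replicate = seq_len(n_per_cell), B = seq_len(J),
                      A = seq_len(I))[, c("A", "B", "replicate")]
  y <- mu + a_c[grid$A] + b_c[grid$B] + ab_c[cbind(grid$A, grid$B)] +
    noise(nrow(grid))
  out <- data.frame(A = factor(grid$A, labels = paste0("a", seq_len(I))),
                    B = factor(grid$B, labels = paste0("b", seq_len(J))),
                    replicate = grid$replicate, y = y)
  attr(out, "truth") <- list(mu = mu, a = a_c, b = b_c, ab = ab_c)
  out
}
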