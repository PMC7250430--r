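#' Configuration for a full pipeline run
#'
#' @param out_dir output directory (created if absent).
#' @param stages ordered subset of \code{c("simulate", "fit", "stats",
#'   "classify")}; later stages read the outputs of earlier ones (or
#'   pre-existing files in \code{out_dir}).
#' @param seed master integer seed for simulation.
#' @param design a \code{\link{plate_design}} (used by the simulate stage).
#' @param noise_sd,baseline simulation noise and control baseline
#'   (absorbance units).
#' @param threshold_od,threshold_r2 growth-call thresholds.
#' @param alpha significance level.
#' @param adjustment Dunn adjustment method.
#' @return A \code{run_config} list.
#' @export
run_config <- function(out_dir,
                       stages = c("simulate", "fit", "stats", "classify"),
                       seed = 1L,
                       design = plate_design(),
                       noise_sd = 0.01, baseline = 0.05,
                       threshold_od = 0.05, threshold_r2 = 0.7,
                       alpha = 0.05, adjustment = "none") {
  known <- c("simulate", "fit", "stats", "classify")
  if (!all(stages %in% known)) stop("unknown stage(s): ",
                                    paste(setdiff(stages, known), collapse = ", "))
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must be in (0, 1)")
  structure(list(out_dir = out_dir, stages = stages, seed = as.integer(seed),
                 design = design, noise_sd = noise_sd, baseline = baseline,
                 threshold_od = threshold_od, threshold_r2 = threshold_r2,
                 alpha = alpha, adjustment = adjustment),
            class = "run_config")
}

#' Run the simulate - fit - stats - classify pipeline
#'
#' Executes the enabled stages in order, writing each stage's table before
#' the next reads it, so any stage can be re-run from the files alone:
#' \code{plate.csv} (simulated readings), \code{rates.csv} (per-well fits),
#' \code{effects.tsv} / \code{pairwise.tsv} / \code{letters.tsv}
#' (statistics), \code{groups.tsv} (classification), plus
#' \code{manifest.json} (seed, configuration, file digests, stage log) and
#' \code{report.txt}. Identical configuration and seed reproduce identical
#' outputs byte for byte.
#'
#' @param config a \code{\link{run_config}}.
#' @return Invisibly, a list with the stage log, output paths and the
#'   report lines.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  log <- list()

  if ("simulate" %in% config$stages) {
    truth <- default_ground_truth(config$design, noise_sd = config$noise_sd,
                                  baseline = config$baseline,
                                  seed = config$seed)
    plate <- simulate_plate(config$design, truth)
    write_plate_table(plate, path("plate.csv"))
    log$simulate <- sprintf("simulate: %d wells x %d days written",
                            length(unique(plate$well_id)), config$design$days)
  }
  if ("fit" %in% config$stages) {
    plate <- read_plate_table(path("plate.csv"))
    rates <- fit_plate(plate, threshold_od = config$threshold_od,
                       threshold_r2 = config$threshold_r2)
    write_rate_table(rates, path("rates.csv"))
    log$fit <- sprintf("fit: %d wells, %d converged, %d growth calls",
                       nrow(rates), sum(rates$fit_ok), sum(rates$growth_flag))
  }
  if ("stats" %in% config$stages) {
    rates <- read_rate_table(path("rates.csv"))
    st <- growth_rate_stats(rates, alpha = config$alpha,
                            adjustment = config$adjustment)
    tabs <- tabulate_growth_stats(st)
    for (nm in names(tabs)) {
      utils::write.table(tabs[[nm]], path(paste0(nm, ".tsv")), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    dropped <- sum(vapply(st, function(s)
      length(s$dropped_levels$pH) + length(s$dropped_levels$temperature), 1L))
    log$stats <- sprintf("stats: %d strata analysed, %d factor levels dropped as no-growth",
                         length(st), dropped)
  }
  if ("classify" %in% config$stages) {
    rates <- read_rate_table(path("rates.csv"))
    cls <- classify_rate_table(rates)
    utils::write.table(cls, path("groups.tsv"), sep = "\t", row.names = FALSE,
                       quote = FALSE)
    log$classify <- sprintf("classify: %d organism(s) labelled", nrow(cls))
  }

  outputs <- list.files(config$out_dir, pattern = "\\.(csv|tsv)$",
                        full.names = TRUE)
  manifest <- list(
    package = "ventgrowth",
    version = as.character(utils::packageVersion("ventgrowth")),
    seed = config$seed,
    stages = config$stages,
    settings = config[c("noise_sd", "baseline", "threshold_od",
                        "threshold_r2", "alpha", "adjustment")],
    digests = as.list(tools::md5sum(outputs)),
    log = log
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  report <- character()
  if (file.exists(path("rates.csv"))) {
    report <- render_report(config$out_dir)
    writeLines(report, path("report.txt"))
  }
  invisible(list(log = log, outputs = outputs, report = report))
}

#' Render a plain-text summary report from pipeline outputs
#'
#' Reads the tables in an output directory and renders, per organism, its
#' growth ranges, the per-level significance letters and its response-group
#' label, ending with the group tally. Rendering is deterministic and
#' idempotent: re-rendering the same directory gives identical text.
#'
#' @param out_dir directory holding pipeline outputs (needs at least
#'   \code{rates.csv}).
#' @return Character vector of report lines.
#' @export
render_report <- function(out_dir) {
  rates_path <- file.path(out_dir, "rates.csv")
  if (!file.exists(rates_path)) stop("missing table: ", rates_path)
  rates <- read_rate_table(rates_path)
  lines <- c("Growth phenotyping report", "=========================", "")
  if (nrow(rates) == 0) return(lines)

  letters_path <- file.path(out_dir, "letters.tsv")
  letters <- if (file.exists(letters_path))
    utils::read.table(letters_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  groups_path <- file.path(out_dir, "groups.tsv")
  groups <- if (file.exists(groups_path))
    utils::read.table(groups_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL

  for (org in sort(unique(rates$organism))) {
    sub <- rates[rates$organism == org & rates$growth_flag, ]
    lines <- c(lines, paste0("Organism: ", org))
    if (nrow(sub)) {
      lines <- c(lines,
        sprintf("  grows at: salinity {%s} permille, pH {%s}, temperature {%s} C",
                paste(sort(unique(sub$salinity)), collapse = ", "),
                paste(sort(unique(sub$pH)), collapse = ", "),
                paste(sort(unique(sub$temperature)), collapse = ", ")),
        sprintf("  mean rate over growing wells: %.4f 1/day", mean(sub$rate)))
    } else {
      lines <- c(lines, "  no growth under any condition")
    }
    if (!is.null(letters)) {
      sl <- letters[grepl(paste0("^", org, " @ "), letters$stratum), ]
      for (str in unique(sl$stratum)) {
        for (w in unique(sl$within[sl$stratum == str])) {
          part <- sl[sl$stratum == str & sl$within == w, ]
          lines <- c(lines, sprintf("  letters [%s | %s]: %s", str, w,
                                    paste0(part$level, "=", part$letters,
                                           collapse = " ")))
        }
      }
    }
    if (!is.null(groups)) {
      gr <- groups[groups$organism == org, ]
      if (nrow(gr)) lines <- c(lines, paste0("  response group: ", gr$group[1]))
    }
    lines <- c(lines, "")
  }
  if (!is.null(groups)) {
    counts <- group_counts(groups$group)
    lines <- c(lines, "Group counts:",
               sprintf("  %s: %d", names(counts), counts))
  }
  lines
}
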