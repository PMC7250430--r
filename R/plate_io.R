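PLATE_COLS <- c("well_id", "organism", "salinity", "pH", "temperature",
                "replicate", "role", "day", "od630")
RATE_COLS <- c("organism", "salinity", "pH", "temperature", "replicate",
               "a", "k", "d", "xc", "rate", "growth_flag", "fit_ok", "rss")

#' Read a long-format plate table
#'
#' Reads a CSV with one row per (well, day) carrying well metadata and the
#' OD630 reading, validates it, and returns it sorted by well and day.
#' The dialect is fixed (comma separator, header row, UTF-8, no missing
#' values) so files are portable across locales.
#'
#' @param source path to a CSV file, or a connection.
#' @return Validated data frame with the standard plate columns.
#' @export
read_plate_table <- function(source) {
  tab <- utils::read.csv(source, stringsAsFactors = FALSE)
  missing <- setdiff(PLATE_COLS, names(tab))
  if (length(missing)) stop("plate table missing column(s): ",
                            paste(missing, collapse = ", "))
  tab <- tab[, PLATE_COLS]
  for (col in c("salinity", "pH", "temperature", "replicate", "day", "od630")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) stop("non-numeric or missing '", col, "' at row ", bad[1])
    tab[[col]] <- v
  }
  dup <- which(duplicated(tab[, c("well_id", "day")]))
  if (length(dup)) stop("duplicated (well_id, day) pair at row ", dup[1],
                        ": ", tab$well_id[dup[1]], " day ", tab$day[dup[1]])
  tab <- tab[order(tab$well_id, tab$day), ]
  rownames(tab) <- NULL
  tab
}

#' Write a plate or rate table to CSV
#'
#' Full-precision CSV output with a stable column order; reading the file
#' back yields the original values.
#'
#' @param table a plate table or growth-rate table.
#' @param sink output path or connection.
#' @return Invisibly, the path written.
#' @export
write_plate_table <- function(table, sink) {
  missing <- setdiff(PLATE_COLS, names(table))
  if (length(missing)) stop("plate table missing column(s): ",
                            paste(missing, collapse = ", "))
  utils::write.csv(format_full(table[, PLATE_COLS]), sink, row.names = FALSE,
                   quote = TRUE)
  invisible(sink)
}

#' @rdname write_plate_table
#' @export
write_rate_table <- function(table, sink) {
  missing <- setdiff(RATE_COLS, names(table))
  if (length(missing)) stop("rate table missing column(s): ",
                            paste(missing, collapse = ", "))
  utils::write.csv(format_full(table[, RATE_COLS]), sink, row.names = FALSE,
                   quote = TRUE)
  invisible(sink)
}

# render numerics at full double precision so round-trips are exact
format_full <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  df
}

#' Read a growth-rate table written by \code{write_rate_table}
#' @param source path or connection.
#' @return Data frame with the standard rate columns.
#' @export
read_rate_table <- function(source) {
  tab <- utils::read.csv(source, stringsAsFactors = FALSE)
  missing <- setdiff(RATE_COLS, names(tab))
  if (length(missing)) stop("rate table missing column(s): ",
                            paste(missing, collapse = ", "))
  for (col in c("growth_flag", "fit_ok")) tab[[col]] <- as.logical(tab[[col]])
  tab
}

#' Blank-subtract inoculated wells against their treatment controls
#'
#' Subtracts, day by day, the mean OD of the uninoculated control wells of
#' the same (salinity, pH, temperature) treatment from each inoculated
#' well's OD. Control matching ignores the organism label: one control set
#' per treatment serves every organism. Negative values are retained, not
#' clamped, because clamping would bias early-time noise upwards.
#'
#' @param plate a long-format plate table containing both inoculated and
#'   control rows.
#' @return The inoculated rows with \code{od630} replaced by the
#'   blank-subtracted signal and \code{role} set to
#'   \code{"blank_subtracted"}.
#' @export
blank_subtract <- function(plate) {
  missing <- setdiff(PLATE_COLS, names(plate))
  if (length(missing)) stop("plate table missing column(s): ",
                            paste(missing, collapse = ", "))
  inoc <- plate[plate$role == "inoculated", ]
  ctrl <- plate[plate$role == "control", ]
  if (nrow(inoc) == 0) stop("no inoculated wells in table")
  if (nrow(ctrl) == 0) stop("no control wells in table: cannot blank-subtract")
  ckey <- paste(ctrl$salinity, ctrl$pH, ctrl$temperature, ctrl$day, sep = "\r")
  cmean <- tapply(ctrl$od630, ckey, mean)
  ikey <- paste(inoc$salinity, inoc$pH, inoc$temperature, inoc$day, sep = "\r")
  m <- cmean[ikey]
  if (anyNA(m)) {
    bad <- inoc[which(is.na(m))[1], ]
    stop("no matching control for treatment salinity=", bad$salinity,
         " pH=", bad$pH, " temperature=", bad$temperature, " day=", bad$day)
  }
  # every inoculated day must be matched AND every well must get a complete grid
  per_well_days <- tapply(inoc$day, inoc$well_id, length)
  per_ctrl_days <- tapply(ctrl$day, paste(ctrl$salinity, ctrl$pH,
                                          ctrl$temperature, ctrl$well_id,
                                          sep = "\r"), length)
  if (length(unique(per_ctrl_days)) > 1 || length(unique(per_well_days)) > 1)
    stop("mismatched time grids between wells")
  inoc$od630 <- inoc$od630 - as.numeric(m)
  inoc$role <- "blank_subtracted"
  rownames(inoc) <- NULL
  inoc
}

#' Fit growth curves to every well of a plate
#'
#' Blank-subtracts a plate table (if controls are present) and fits the
#' Richards model to every inoculated well, producing the replicate-level
#' growth-rate table that feeds the factorial statistics. No-growth wells
#' are retained with rate 0 and \code{growth_flag = FALSE}.
#'
#' @param plate long-format plate table (see \code{\link{read_plate_table}}).
#' @param threshold_od,threshold_r2 growth-call thresholds, see
#'   \code{\link{call_growth}}.
#' @param ... further arguments to \code{\link{richards_fit}}.
#' @return A growth-rate table: one row per well with columns organism,
#'   salinity, pH, temperature, replicate, a, k, d, xc, rate, growth_flag,
#'   fit_ok, rss.
#' @export
fit_plate <- function(plate, threshold_od = 0.05, threshold_r2 = 0.7, ...) {
  if (any(plate$role == "control")) plate <- blank_subtract(plate)
  plate <- plate[plate$role %in% c("inoculated", "blank_subtracted"), ]
  if (nrow(plate) == 0) stop("no wells to fit")
  rows <- split(plate, plate$well_id)
  res <- lapply(rows, function(w) {
    w <- w[order(w$day), ]
    fit <- richards_fit(w$day, w$od630, threshold_od = threshold_od,
                        threshold_r2 = threshold_r2, ...)
    p <- fit$params
    data.frame(organism = w$organism[1], salinity = w$salinity[1],
               pH = w$pH[1], temperature = w$temperature[1],
               replicate = w$replicate[1],
               a = unname(p["a"]), k = unname(p["k"]), d = unname(p["d"]),
               xc = unname(p["xc"]), rate = fit$rate,
               growth_flag = fit$growth, fit_ok = fit$converged,
               rss = fit$rss, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$organism, out$salinity, out$pH, out$temperature,
                   out$replicate), ]
  rownames(out) <- NULL
  out
}
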