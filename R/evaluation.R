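#' Detection efficiency per range bin
#'
#' For each half-open range bin `(a, b]`, the flight time is the time the
#' reference distance lies in the bin and the detection time is the part of
#' it with a detection; both are measured in whole frames at the configured
#' frame rate. Efficiency is `100 * detection_time / flight_time`, rounded
#' half-up to integer percent; bins the target never visited are reported
#' as missing.
#'
#' @param detected_times timestamps (s) at which a detection was made; must
#'   be a subset of the reference timestamps.
#' @param reference a reference track (data.frame with columns `t`, `D`).
#' @param bins numeric vector of bin breaks in m, e.g.
#'   `seq(0, 350, by = 50)` for the bins `(0,50], (50,100], ...`.
#' @param fps frame rate in Hz used to convert frame counts to seconds
#'   (default 15).
#' @return a data.frame with columns `bin_low`, `bin_high` (m),
#'   `flight_time`, `detection_time` (s), `efficiency` (percent, `NA` for
#'   unvisited bins).
#' @examples
#' ref <- data.frame(t = 0:9, D = c(rep(40, 4), rep(60, 6)))
#' detection_efficiency(c(0:2, 4:8), ref, c(0, 50, 100), fps = 1)
#' @export
detection_efficiency <- function(detected_times, reference, bins, fps = 15) {
  if (length(bins) < 2) stop("need at least two bin breaks")
  key <- function(t) round(t * 1e6)
  if (!all(key(detected_times) %in% key(reference$t))) {
    stop("detected_times must be a subset of the reference timestamps")
  }
  detected <- key(reference$t) %in% key(detected_times)
  idx <- findInterval(reference$D, bins, left.open = TRUE)  # (a, b] bins
  inside <- idx >= 1 & idx <= length(bins) - 1 & reference$D > bins[1]
  flight <- tabulate(idx[inside], nbins = length(bins) - 1)
  det <- tabulate(idx[inside & detected], nbins = length(bins) - 1)
  data.frame(
    bin_low = bins[-length(bins)],
    bin_high = bins[-1],
    flight_time = flight / fps,
    detection_time = det / fps,
    efficiency = ifelse(flight > 0, round_half_away(100 * det / flight), NA))
}

population_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Localization accuracy statistics against a reference track
#'
#' Means and population (N-denominator) standard deviations of distance and
#' altitude for the system track and the reference track, plus the absolute
#' accuracy `|mean_sys - mean_ref|` and relative accuracy
#' `100 * |mean_sys - mean_ref| / mean_ref` for both quantities.
#'
#' @param system_track data.frame of triangulated localizations with
#'   columns `D`, `H` (e.g. from [triangulate_distance()]).
#' @param reference a reference track with columns `D`, `H`.
#' @return a one-row data.frame with columns `mean_D_ref`, `sd_D_ref`,
#'   `mean_H_ref`, `sd_H_ref`, `N` (system sample count), `mean_D_sys`,
#'   `sd_D_sys`, `mean_H_sys`, `sd_H_sys` (m), `dD_abs`, `dH_abs` (m),
#'   `dD_rel`, `dH_rel` (percent), all at full precision (round for table
#'   display with [round_half_away()]).
#' @export
localization_stats <- function(system_track, reference) {
  if (nrow(system_track) == 0 || nrow(reference) == 0) {
    stop("system and reference tracks must be non-empty")
  }
  mdr <- mean(reference$D); mhr <- mean(reference$H)
  mds <- mean(system_track$D); mhs <- mean(system_track$H)
  data.frame(
    mean_D_ref = mdr, sd_D_ref = population_sd(reference$D),
    mean_H_ref = mhr, sd_H_ref = population_sd(reference$H),
    N = nrow(system_track),
    mean_D_sys = mds, sd_D_sys = population_sd(system_track$D),
    mean_H_sys = mhs, sd_H_sys = population_sd(system_track$H),
    dD_abs = abs(mds - mdr), dH_abs = abs(mhs - mhr),
    dD_rel = 100 * abs(mds - mdr) / mdr,
    dH_rel = 100 * abs(mhs - mhr) / mhr)
}

#' Absolute and relative accuracy from two means
#'
#' Table-entry helper: `abs = |mean_sys - mean_ref|` and
#' `rel = 100 * abs / mean_ref`, rounded half-up to the requested number of
#' decimals.
#'
#' @param mean_ref,mean_sys reference and system means (same units).
#' @param digits decimals kept in the rounded values (default 1).
#' @return `list(abs, rel)`.
#' @examples
#' accuracy_from_means(46.4, 45.6) # abs 0.8 m, rel 1.7 percent
#' @export
accuracy_from_means <- function(mean_ref, mean_sys, digits = 1) {
  a <- abs(mean_sys - mean_ref)
  list(abs = round_half_away(a, digits),
       rel = round_half_away(100 * a / mean_ref, digits))
}

#' Classification confusion counts and per-class reliability
#'
#' 3x3 confusion matrix of true versus assigned size class, with the
#' per-class reliability (the diagonal as a percentage of the row total,
#' rounded half-up to one decimal).
#'
#' @param true,predicted vectors of class labels (`"small"`, `"medium"`,
#'   `"large"`); factors or characters. Unknown labels are an error.
#' @return an object of class `confusion_counts`: `list(counts, reliability)`
#'   where `counts` is the 3x3 matrix (rows = true class) and `reliability`
#'   a named numeric vector in percent (`NA` for classes never seen).
#' @examples
#' classification_confusion(rep("small", 5), rep("small", 5))
#' @export
classification_confusion <- function(true, predicted) {
  lv <- c("small", "medium", "large")
  if (length(true) == 0) stop("no classification events")
  if (length(true) != length(predicted)) {
    stop("true and predicted must have the same length")
  }
  bad <- setdiff(unique(c(as.character(true), as.character(predicted))), lv)
  if (length(bad) > 0) stop("unknown class label(s): ",
                            paste(bad, collapse = ", "))
  counts <- table(factor(true, lv), factor(predicted, lv))
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(true = lv, predicted = lv))
  totals <- rowSums(counts)
  reliability <- ifelse(totals > 0,
                        round_half_away(100 * diag(counts) / totals, 1), NA)
  names(reliability) <- lv
  structure(list(counts = counts, reliability = reliability),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  print(x$counts)
  cat("reliability (%):",
      paste(names(x$reliability), format(x$reliability), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write an evaluation report
#'
#' Deterministic serialization of the evaluation tables: `report.json` plus
#' one CSV per supplied table (`table4.csv` range-bin efficiencies,
#' `table5.csv` localization statistics, `table6.csv` confusion counts).
#' Empty sections are allowed and serialized as empty.
#'
#' @param bundle a list with any of `range_stats` (from
#'   [detection_efficiency()]), `scenario_stats` (from
#'   [localization_stats()], one row per scenario), `confusion` (from
#'   [classification_confusion()]) and `metadata` (a list of run metadata,
#'   e.g. seed and config hash).
#' @param out_dir output directory (created if needed).
#' @return the path of `report.json`, invisibly.
#' @export
report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(metadata = bundle$metadata %||% list())
  if (!is.null(bundle$range_stats)) {
    utils::write.csv(bundle$range_stats, file.path(out_dir, "table4.csv"),
                     row.names = FALSE)
    json$range_stats <- bundle$range_stats
  }
  if (!is.null(bundle$scenario_stats)) {
    utils::write.csv(bundle$scenario_stats, file.path(out_dir, "table5.csv"),
                     row.names = FALSE)
    json$scenario_stats <- bundle$scenario_stats
  }
  if (!is.null(bundle$confusion)) {
    cm <- as.data.frame.matrix(bundle$confusion$counts)
    cm <- cbind(true = rownames(bundle$confusion$counts), cm)
    utils::write.csv(cm, file.path(out_dir, "table6.csv"), row.names = FALSE)
    json$confusion <- list(counts = cm,
                           reliability = as.list(bundle$confusion$reliability))
  }
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}
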