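#' Excurrent flow from dye-front measurements
#'
#' The dye-speed method estimates the volume flow through an osculum as the
#' product of the excurrent jet speed and the osculum cross-sectional area,
#' assuming plug flow. Jet speed per replicate is dye-front distance over
#' transit time; replicate speeds are averaged per sponge.
#'
#' @param measurements Data frame with columns `sponge`, `distance_mm`
#'   (dye-front travel distance), `time_s` (transit time) and
#'   `osculum_area_mm2` (constant within sponge).
#' @return A tibble per sponge: `n_replicates`, `jet_speed_mm_s` (mean),
#'   `jet_speed_sd`, `osculum_area_mm2`, `flow_mm3_s` and `flow_um3_s`.
#' @examples
#' excurrent_flow(tibble::tibble(
#'   sponge = "s1", distance_mm = 10, time_s = 2, osculum_area_mm2 = 1))
#' @export
excurrent_flow <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  required <- c("sponge", "distance_mm", "time_s", "osculum_area_mm2")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(m$time_s <= 0)) {
    stop("invalid measurement: transit time must be positive", call. = FALSE)
  }
  if (any(m$distance_mm <= 0)) {
    stop("invalid measurement: dye-front distance must be positive",
         call. = FALSE)
  }
  m |>
    dplyr::mutate(speed = .data$distance_mm / .data$time_s) |>
    dplyr::group_by(.data$sponge) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      jet_speed_mm_s = mean(.data$speed),
      jet_speed_sd = stats::sd(.data$speed),
      osculum_area_mm2 = .data$osculum_area_mm2[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      flow_mm3_s = .data$jet_speed_mm_s * .data$osculum_area_mm2,
      flow_um3_s = .data$flow_mm3_s * 1e9
    )
}

#' Per-ostium and per-choanocyte pumping rates
#'
#' Divides a whole-sponge exhalant flux among its ostia, and each ostium's
#' share among the choanocytes of its pumping unit.
#'
#' @param total_flux_um3_s Whole-sponge excurrent flux (um^3/s).
#' @param n_ostia Estimated total number of ostia.
#' @param choanocytes_per_ostium Choanocytes per pumping unit (24 in the
#'   reference chamber morphology).
#' @param leucon_range Published per-choanocyte range (um^3/s) used for the
#'   comparability flag.
#' @return One-row tibble: `q_ost_um3_s`, `q_ch_um3_s`,
#'   `q_ch_in_leucon_range`.
#' @export
per_unit_rates <- function(total_flux_um3_s, n_ostia,
                           choanocytes_per_ostium = 24,
                           leucon_range = c(17, 236)) {
  if (n_ostia <= 0 || choanocytes_per_ostium <= 0) {
    stop("ostium and choanocyte counts must be positive", call. = FALSE)
  }
  q_ost <- total_flux_um3_s / n_ostia
  q_ch <- q_ost / choanocytes_per_ostium
  tibble::tibble(
    q_ost_um3_s = q_ost,
    q_ch_um3_s = q_ch,
    q_ch_in_leucon_range = q_ch >= leucon_range[1] & q_ch <= leucon_range[2]
  )
}

#' Bead-calibrated prey concentrations from cytometry counts
#'
#' Every sample is spiked with beads of known stock concentration; the
#' analysed volume is the bead count divided by the stock concentration, and
#' each prey class concentration is its event count over that volume.
#'
#' @param counts Data frame with a `bead_count` column plus one column per
#'   prey-class event count (e.g. `euk`, `hna`, `lna`); any other columns are
#'   carried through as identifiers.
#' @param bead_stock_per_ul Bead stock concentration (beads/uL).
#' @param classes Names of the prey-class count columns.
#' @return The input tibble with `volume_ul` and one `<class>_per_ul`
#'   concentration column per class.
#' @export
bead_calibrated_concentration <- function(counts, bead_stock_per_ul,
                                          classes = c("euk", "hna", "lna")) {
  x <- tibble::as_tibble(counts)
  missing_cols <- setdiff(c("bead_count", classes), names(x))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$bead_count <= 0)) {
    stop("calibration error: bead count must be positive in every sample",
         call. = FALSE)
  }
  if (bead_stock_per_ul <= 0) {
    stop("calibration error: bead stock concentration must be positive",
         call. = FALSE)
  }
  x$volume_ul <- x$bead_count / bead_stock_per_ul
  for (cl in classes) {
    x[[paste0(cl, "_per_ul")]] <- x[[cl]] / x$volume_ul
  }
  x
}

#' Retention efficiency from paired concentrations
#'
#' In-Ex retention efficiency in percent, `100 (C_in - C_ex) / C_in`.
#' Negative values (exhaled exceeding inhaled) are preserved so that medians
#' across pairs stay unbiased.
#'
#' @param c_in,c_ex Inhaled and exhaled concentrations (same units).
#' @return Retention in percent, vectorised.
#' @export
retention_efficiency <- function(c_in, c_ex) {
  if (any(c_in <= 0)) {
    stop("inhaled concentration must be positive", call. = FALSE)
  }
  100 * (c_in - c_ex) / c_in
}

#' Paired In-Ex retention per sample pair and prey class
#'
#' Computes bead-calibrated concentrations for a paired inhaled/exhaled
#' cytometry table and the per-pair retention efficiency of each prey class.
#'
#' @param inex Data frame with columns `sponge`, `pair`, `direction`
#'   (`"in"`/`"ex"`), `bead_count`, and one count column per prey class.
#' @inheritParams bead_calibrated_concentration
#' @return A tibble with one row per (sponge, pair, class):
#'   `retention_pct`, plus the paired concentrations `c_in_per_ul`,
#'   `c_ex_per_ul`.
#' @export
inex_retention <- function(inex, bead_stock_per_ul,
                           classes = c("euk", "hna", "lna")) {
  x <- tibble::as_tibble(inex)
  required <- c("sponge", "pair", "direction", "bead_count", classes)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- !x$direction %in% c("in", "ex")
  if (any(bad)) {
    stop("malformed row(s) ", paste(which(bad), collapse = ", "),
         ": direction must be \"in\" or \"ex\"", call. = FALSE)
  }
  conc <- bead_calibrated_concentration(x, bead_stock_per_ul, classes)
  long <- conc |>
    dplyr::select("sponge", "pair", "direction",
                  dplyr::all_of(paste0(classes, "_per_ul"))) |>
    tidyr::pivot_longer(dplyr::all_of(paste0(classes, "_per_ul")),
                        names_to = "class", values_to = "conc_per_ul") |>
    dplyr::mutate(class = sub("_per_ul$", "", .data$class)) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "conc_per_ul")
  if (!all(c("in", "ex") %in% names(long)) || anyNA(long$`in`) || anyNA(long$ex)) {
    stop("every (sponge, pair) must have one inhaled and one exhaled sample",
         call. = FALSE)
  }
  long |>
    dplyr::rename(c_in_per_ul = "in", c_ex_per_ul = "ex") |>
    dplyr::mutate(
      retention_pct = retention_efficiency(.data$c_in_per_ul, .data$c_ex_per_ul)
    )
}

#' Box-plot summary of retention efficiencies per prey class
#'
#' Summarises per-pair retention values the way retention box plots are
#' drawn: median, 25th/75th percentiles (linear-interpolation quartiles),
#' whiskers extending to the most extreme data points within 1.5 x IQR of
#' the box, and outliers beyond the whiskers. The mean and its standard
#' error (and the s.d.) are reported alongside.
#'
#' @param retention Data frame with columns `class` and `retention_pct`,
#'   e.g. from [inex_retention()].
#' @param min_pairs Minimum pairs required per class.
#' @return A `retention_summary`: tibble with one row per class (`n`,
#'   `median`, `q1`, `q3`, `iqr`, `whisker_lo`, `whisker_hi`, `mean`, `se`,
#'   `sd`, `n_outliers`) carrying the outlier values in the list-column
#'   `outliers`.
#' @export
retention_summary <- function(retention, min_pairs = 3) {
  x <- tibble::as_tibble(retention)
  if (!all(c("class", "retention_pct") %in% names(x))) {
    stop("retention must have columns `class` and `retention_pct`",
         call. = FALSE)
  }
  out <- x |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(res = list(box_stats(.data$retention_pct)),
                     .groups = "drop") |>
    tidyr::unnest_wider("res")
  out$outliers <- lapply(out$outliers, `[[`, 1)
  if (any(out$n < min_pairs)) {
    stop(sprintf("need at least %d pairs per class", min_pairs), call. = FALSE)
  }
  class(out) <- c("retention_summary", class(out))
  out
}

# Box statistics with type-7 quartiles and the 1.5 x IQR whisker rule.
box_stats <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- v >= lo_fence & v <= hi_fence
  list(
    n = length(v),
    median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
    whisker_lo = min(v[inside]),
    whisker_hi = max(v[inside]),
    mean = mean(v),
    se = stats::sd(v) / sqrt(length(v)),
    sd = stats::sd(v),
    n_outliers = sum(!inside),
    outliers = list(sort(v[!inside]))
  )
}

#' @export
print.retention_summary <- function(x, ...) {
  cat("Retention efficiency summary (%)\n")
  df <- as.data.frame(x[, c("class", "n", "median", "q1", "q3",
                            "mean", "se", "n_outliers")])
  df[, sapply(df, is.numeric)] <- round(df[, sapply(df, is.numeric)], 1)
  print(df, row.names = FALSE)
  invisible(x)
}
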