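#' Build the default radial transect layout for a set of plots
#'
#' The monitored plot design is three 100-m transects laid out as spokes
#' from the plot center (where the meteorological tower stands) at 60-degree
#' intervals. Along-transect positions are recorded in integer centimeters
#' from the center (position 0) outward.
#'
#' @param plot_ids Character vector of plot identifiers.
#' @param azimuth_deg Transect azimuths in degrees, `[0, 360)`.
#' @param length_cm Transect length in integer cm (default 10000 = 100 m).
#' @return A tibble with columns `plot_id`, `transect_id`, `azimuth_deg`,
#'   `length_cm`.
#' @export
default_layout <- function(plot_ids, azimuth_deg = c(0, 60, 120),
                           length_cm = TRANSECT_LENGTH_CM) {
  stopifnot(length(azimuth_deg) >= 1, all(azimuth_deg >= 0 & azimuth_deg < 360),
            length_cm > 0)
  tidyr::crossing(
    plot_id = as.character(plot_ids),
    tibble::tibble(
      transect_id = paste0("T", seq_along(azimuth_deg)),
      azimuth_deg = as.numeric(azimuth_deg),
      length_cm = as.integer(length_cm)
    )
  )
}

#' Assemble and validate a transect study
#'
#' Bundles the layout and the tall record tables of the three field methods
#' (line-point intercept, canopy gap intercept, vegetation height) into a
#' single validated object covering one or more plots and sampling events.
#'
#' @param layout Layout table (`plot_id`, `transect_id`, `azimuth_deg`,
#'   `length_cm`).
#' @param lpi LPI table, one row per intercepted layer:
#'   `plot_id`, `event_id`, `transect_id`, `position_cm`, `layer`, `code`.
#'   Pins with no interception appear as a single row with code `"NONE"`.
#' @param gap Canopy gap table: `plot_id`, `event_id`, `transect_id`,
#'   `start_cm`, `end_cm`.
#' @param height Height table: `plot_id`, `event_id`, `transect_id`,
#'   `position_cm`, `height_cm` (`NA` height = no rooted plant at the point).
#' @param validate Run full invariant validation (default `TRUE`).
#' @return An object of class `transect_study`: a list with the four input
#'   tables plus `events` (the observed `(plot_id, event_id)` pairs) and
#'   `sampled_layout` (`plot_id`, `event_id`, `transect_id`, `length_cm`),
#'   the per-event sampled transect lengths used as canopy-gap denominators.
#'   Subsampling operations update `sampled_layout`.
#' @export
transect_study <- function(layout, lpi, gap, height, validate = TRUE) {
  layout <- coerce_cols(layout, "layout",
    c(plot_id = "character", transect_id = "character",
      azimuth_deg = "numeric", length_cm = "integer"))
  lpi <- coerce_cols(lpi, "lpi",
    c(plot_id = "character", event_id = "character", transect_id = "character",
      position_cm = "integer", layer = "character", code = "character"))
  gap <- coerce_cols(gap, "gap",
    c(plot_id = "character", event_id = "character", transect_id = "character",
      start_cm = "integer", end_cm = "integer"))
  height <- coerce_cols(height, "height",
    c(plot_id = "character", event_id = "character", transect_id = "character",
      position_cm = "integer", height_cm = "numeric"))

  events <- dplyr::distinct(
    dplyr::bind_rows(
      dplyr::select(lpi, "plot_id", "event_id"),
      dplyr::select(gap, "plot_id", "event_id"),
      dplyr::select(height, "plot_id", "event_id")
    )
  )
  events <- dplyr::arrange(events, .data$plot_id, .data$event_id)
  sampled_layout <- dplyr::inner_join(
    events, dplyr::select(layout, "plot_id", "transect_id", "length_cm"),
    by = "plot_id", relationship = "many-to-many"
  )

  study <- structure(
    list(layout = layout, lpi = lpi, gap = gap, height = height,
         events = events, sampled_layout = sampled_layout),
    class = "transect_study"
  )
  if (validate) validate_study(study)
  study
}

#' @export
print.transect_study <- function(x, ...) {
  cat("<transect_study>\n")
  cat("  plots:  ", dplyr::n_distinct(x$events$plot_id), "\n")
  cat("  events: ", nrow(x$events), "\n")
  cat("  LPI rows:", nrow(x$lpi), " gap rows:", nrow(x$gap),
      " height rows:", nrow(x$height), "\n")
  invisible(x)
}

coerce_cols <- function(df, table_name, spec) {
  missing <- setdiff(names(spec), names(df))
  if (length(missing) > 0) {
    stop_transectopt(
      sprintf("table '%s' is missing required column(s): %s",
              table_name, paste(missing, collapse = ", ")),
      "transectopt_format_error")
  }
  df <- tibble::as_tibble(df)[names(spec)]
  for (col in names(spec)) {
    df[[col]] <- switch(spec[[col]],
      character = as.character(df[[col]]),
      integer = {
        v <- df[[col]]
        if (is.character(v)) v <- suppressWarnings(as.numeric(v))
        iv <- suppressWarnings(as.integer(round(v)))
        if (any(!is.na(v) & (is.na(iv) | abs(v - iv) > 1e-8))) {
          stop_transectopt(
            sprintf("table '%s' column '%s' must be integer-valued",
                    table_name, col),
            "transectopt_format_error")
        }
        iv
      },
      numeric = suppressWarnings(as.numeric(df[[col]]))
    )
  }
  df
}

#' Validate the invariants of a transect study
#'
#' Checks positions against the base measurement intervals (pins on 25-cm
#' multiples, height points on 200-cm multiples), gap geometry (end after
#' start, 5-cm minimum, within the transect, non-overlapping), and that every
#' record references a transect in the layout. Violations raise a
#' `transectopt_validation_error` naming the offending rows.
#'
#' @param study A `transect_study`.
#' @return The study, invisibly, if valid.
#' @export
validate_study <- function(study) {
  fail <- function(msg) stop_transectopt(msg, "transectopt_validation_error")
  layout <- study$layout

  if (any(layout$length_cm <= 0)) fail("layout: length_cm must be > 0")
  if (any(layout$azimuth_deg < 0 | layout$azimuth_deg >= 360)) {
    fail("layout: azimuth_deg must be in [0, 360)")
  }
  if (anyDuplicated(layout[c("plot_id", "transect_id")]) > 0) {
    fail("layout: duplicated (plot_id, transect_id)")
  }

  key <- function(df) paste(df$plot_id, df$transect_id)
  lkey <- key(layout)
  for (tbl in c("lpi", "gap", "height")) {
    bad <- which(!(key(study[[tbl]]) %in% lkey))
    if (length(bad) > 0) {
      fail(sprintf("%s: rows %s reference a (plot_id, transect_id) absent from layout",
                   tbl, paste(utils::head(bad, 5), collapse = ", ")))
    }
  }

  lpi <- study$lpi
  bad <- which(lpi$position_cm <= 0 | lpi$position_cm %% LPI_BASE_CM != 0)
  if (length(bad) > 0) {
    fail(sprintf("lpi: rows %s have position_cm that is not a positive multiple of %d cm",
                 paste(utils::head(bad, 5), collapse = ", "), LPI_BASE_CM))
  }

  hgt <- study$height
  bad <- which(hgt$position_cm <= 0 | hgt$position_cm %% HEIGHT_BASE_CM != 0)
  if (length(bad) > 0) {
    fail(sprintf("height: rows %s have position_cm that is not a positive multiple of %d cm",
                 paste(utils::head(bad, 5), collapse = ", "), HEIGHT_BASE_CM))
  }
  if (any(hgt$height_cm < 0, na.rm = TRUE)) fail("height: height_cm must be >= 0")

  gap <- study$gap
  bad <- which(gap$end_cm <= gap$start_cm)
  if (length(bad) > 0) {
    fail(sprintf("gap: rows %s have end before (or at) start",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(gap$end_cm - gap$start_cm < MIN_GAP_CM)
  if (length(bad) > 0) {
    fail(sprintf("gap: rows %s are shorter than the %d-cm minimum gap",
                 paste(utils::head(bad, 5), collapse = ", "), MIN_GAP_CM))
  }
  if (any(gap$start_cm < 0)) fail("gap: start_cm must be >= 0")
  glen <- dplyr::left_join(gap, study$layout[c("plot_id", "transect_id", "length_cm")],
                           by = c("plot_id", "transect_id"))
  bad <- which(glen$end_cm > glen$length_cm)
  if (length(bad) > 0) {
    fail(sprintf("gap: rows %s extend beyond the transect length",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (nrow(gap) > 1) {
    ord <- order(gap$plot_id, gap$event_id, gap$transect_id, gap$start_cm)
    g <- gap[ord, ]
    same <- with(g, plot_id[-1] == plot_id[-nrow(g)] &
                   event_id[-1] == event_id[-nrow(g)] &
                   transect_id[-1] == transect_id[-nrow(g)])
    overl <- which(same & g$start_cm[-1] < g$end_cm[-nrow(g)])
    if (length(overl) > 0) {
      fail(sprintf("gap: overlapping gaps on transect %s (plot %s, event %s)",
                   g$transect_id[overl[1] + 1], g$plot_id[overl[1] + 1],
                   g$event_id[overl[1] + 1]))
    }
  }
  invisible(study)
}

#' Read the tall method tables of a study from CSV files
#'
#' Reads the four comma-separated tables distributed by monitoring data
#' commons (`lpi.csv`, `gap.csv`, `height.csv`, `layout.csv`) and returns a
#' validated [transect_study()]. Blank `height_cm` cells are read as `NA`
#' (no rooted plant at the point).
#'
#' @param lpi_path,gap_path,height_path,layout_path File paths.
#' @return A validated `transect_study`.
#' @export
read_method_tables <- function(lpi_path, gap_path, height_path, layout_path) {
  read1 <- function(path) {
    if (!file.exists(path)) {
      stop_transectopt(sprintf("file not found: %s", path),
                       "transectopt_format_error")
    }
    utils::read.csv(path, colClasses = "character", check.names = TRUE,
                    na.strings = c("NA", ""))
  }
  transect_study(
    layout = read1(layout_path),
    lpi = read1(lpi_path),
    gap = read1(gap_path),
    height = read1(height_path)
  )
}

#' Write a study's method tables to CSV files
#'
#' Inverse of [read_method_tables()]: writes `lpi.csv`, `gap.csv`,
#' `height.csv` and `layout.csv` under `dir`. Integer-centimeter positions
#' round-trip exactly.
#'
#' @param study A `transect_study`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(study$lpi, file.path(dir, "lpi.csv"), row.names = FALSE, na = "")
  utils::write.csv(study$gap, file.path(dir, "gap.csv"), row.names = FALSE, na = "")
  utils::write.csv(study$height, file.path(dir, "height.csv"), row.names = FALSE, na = "")
  utils::write.csv(study$layout, file.path(dir, "layout.csv"), row.names = FALSE, na = "")
  invisible(dir)
}

#' Read a study written by [write_study()]
#' @param dir Directory containing the four CSV files.
#' @return A validated `transect_study`.
#' @export
read_study <- function(dir) {
  read_method_tables(
    lpi_path = file.path(dir, "lpi.csv"),
    gap_path = file.path(dir, "gap.csv"),
    height_path = file.path(dir, "height.csv"),
    layout_path = file.path(dir, "layout.csv")
  )
}

#' Default set of non-plant layer codes
#'
#' Layer codes that never count as plant species in cover or richness
#' indicators: the no-interception marker plus common surface and litter
#' codes. Code dialects vary between monitoring programs, so the set is
#' configuration, not hard-coded: extend it with `extra` or replace it
#' entirely.
#'
#' @param extra Additional codes to treat as non-plant.
#' @return Character vector of codes.
#' @export
nonplant_codes <- function(extra = character()) {
  unique(c(
    "NONE", "N",            # no interception
    "S", "BR", "R", "GR", "CB", "ST", "BY",  # soil, bedrock, rock fragments
    "L", "HL", "WL", "NL", "EL", "AL", "DS", # litter and duff
    "M", "LC", "W", "VL", "AM",              # moss, lichen, water, vagrant lichen
    as.character(extra)
  ))
}

#' Write / read an agreement results table
#'
#' One row per (method, indicator, design, confidence level) with bias, bias
#' CI, variance components, agreement half-width, MOVER outer bounds, pass
#' flags, and effort metrics. Values round-trip through CSV to at least six
#' decimals.
#'
#' @param results Non-empty results tibble (see [run_scenario_grid()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    stop_transectopt("results table is empty", "transectopt_format_error")
  }
  ok <- tryCatch({
    utils::write.csv(results, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_transectopt(sprintf("cannot write results to '%s': %s",
                             path, conditionMessage(ok)),
                     "transectopt_io_error")
  }
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) {
    stop_transectopt(sprintf("file not found: %s", path), "transectopt_io_error")
  }
  tibble::as_tibble(utils::read.csv(path, na.strings = c("NA", "")))
}
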