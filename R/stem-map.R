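#' Build a stem map from a data frame of tree records
#'
#' A stem map is the package's central container: a tibble of tree records
#' (one row per tree) carrying a rectangular [plot_window()] as an attribute.
#' It behaves as an ordinary tibble in dplyr pipelines; the window and label
#' attributes are preserved by the package's own verbs.
#'
#' Required columns: `id` (unique token), `x`, `y` (meters within the
#' window), `species` (free-text code), `dbh` (diameter at breast height,
#' cm, > 0). Optional: `height` (m), `crown_base_height` (m),
#' `crown_consumption` (fraction in \[0, 1\]), `status`
#' (`"alive"`/`"killed"`, post-fire only).
#'
#' @param trees A data frame with at least the required columns.
#' @param window A [plot_window()] (or a length-4 numeric
#'   `c(x_min, x_max, y_min, y_max)`).
#' @param label Optional free-text label (plot name, era).
#' @return A `stem_map`: a tibble subclass with `window` and `label`
#'   attributes.
#' @examples
#' stem_map(
#'   data.frame(id = 1:2, x = c(5, 10), y = c(5, 5),
#'              species = "PIPO", dbh = c(30, 40)),
#'   plot_window(0, 50, 0, 50)
#' )
#' @export
stem_map <- function(trees, window, label = NULL) {
  window <- as_plot_window(window)
  trees <- as_tibble(trees)
  required <- c("id", "x", "y", "species", "dbh")
  missing_cols <- setdiff(required, names(trees))
  if (length(missing_cols) > 0) {
    abort(sprintf("Stem map is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  for (col in c("x", "y", "dbh")) {
    if (!is.numeric(trees[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(trees[[col]]))))
      abort(sprintf("Column `%s` must be numeric (first bad row: %s).",
                    col, if (length(bad)) bad[1] else "?"))
    }
  }
  if (anyDuplicated(trees$id)) {
    dup <- trees$id[duplicated(trees$id)]
    abort(sprintf("Duplicate tree id(s): %s.",
                  paste(unique(head(dup, 5)), collapse = ", ")))
  }
  bad_dbh <- which(!is.finite(trees$dbh) | trees$dbh <= 0)
  if (length(bad_dbh) > 0) {
    abort(sprintf("`dbh` must be > 0; bad row(s): %s.",
                  paste(head(bad_dbh, 5), collapse = ", ")))
  }
  outside <- which(!in_window(trees$x, trees$y, window))
  if (length(outside) > 0) {
    abort(sprintf("%d tree(s) fall outside the window; row(s): %s.",
                  length(outside), paste(head(outside, 5), collapse = ", ")))
  }
  if ("crown_consumption" %in% names(trees)) {
    cc <- trees$crown_consumption
    bad <- which(!is.na(cc) & (cc < 0 | cc > 1))
    if (length(bad) > 0) {
      abort(sprintf("`crown_consumption` must lie in [0, 1]; bad row(s): %s.",
                    paste(head(bad, 5), collapse = ", ")))
    }
  }
  if ("status" %in% names(trees)) {
    bad <- which(!is.na(trees$status) & !trees$status %in% c("alive", "killed"))
    if (length(bad) > 0) {
      abort(sprintf("`status` must be 'alive' or 'killed'; bad row(s): %s.",
                    paste(head(bad, 5), collapse = ", ")))
    }
  }
  new_stem_map(trees, window, label)
}

new_stem_map <- function(trees, window, label = NULL) {
  structure(
    as_tibble(trees),
    window = window,
    label = label,
    class = c("stem_map", class(tibble()))
  )
}

#' Window and label of a stem map
#'
#' @param map A [stem_map()].
#' @return `map_window()` returns the [plot_window()]; `map_label()` the
#'   free-text label (possibly `NULL`).
#' @export
map_window <- function(map) {
  w <- attr(map, "window", exact = TRUE)
  if (is.null(w)) abort("Object has no window attribute; is it a stem_map?")
  w
}

#' @rdname map_window
#' @export
map_label <- function(map) attr(map, "label", exact = TRUE)

#' @export
print.stem_map <- function(x, ...) {
  lbl <- map_label(x)
  cat(sprintf("<stem_map> %d trees in %s%s\n", nrow(x),
              format(map_window(x)),
              if (is.null(lbl)) "" else paste0(" [", lbl, "]")))
  NextMethod()
}

# Rebuild a stem_map around a plain tibble, keeping window/label.
restamp <- function(trees, template) {
  new_stem_map(as_tibble(trees), map_window(template), map_label(template))
}

#' Read a stem map from delimited text
#'
#' Reads a comma- or tab-delimited tree table (header required) and
#' validates it against a window. Column names in the file can be remapped
#' via `columns` so arbitrary deposit layouts can be ingested. Units are
#' meters for coordinates and heights, centimeters for dbh.
#'
#' @param path Path to a delimited text file with a header row naming at
#'   least `id`, `x`, `y`, `species`, `dbh` (after remapping).
#' @param window A [plot_window()], or path handling via `window_config`.
#' @param columns Named character vector mapping standard names to the
#'   file's column names, e.g. `c(dbh = "DBH_CM")`. Unmapped standard names
#'   are looked up verbatim.
#' @param delim Field delimiter; `NULL` guesses from the file extension
#'   (".csv" comma, otherwise tab).
#' @param min_dbh Optional minimum dbh (cm); smaller trees are dropped
#'   before validation (census thresholds differ between historical and
#'   contemporary inventories). Default `NULL` keeps every row.
#' @param drop_outside If `TRUE`, rows outside the window are dropped with a
#'   warning naming how many; if `FALSE` (default) they are an error.
#' @return A validated [stem_map()].
#' @export
read_stem_map <- function(path, window, columns = NULL, delim = NULL,
                          min_dbh = NULL, drop_outside = FALSE) {
  window <- as_plot_window(window)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  std <- c("id", "x", "y", "species", "dbh", "height", "crown_base_height",
           "crown_consumption", "status")
  lookup <- setNames(std, std)
  if (!is.null(columns)) lookup[names(columns)] <- unname(columns)
  present <- lookup[lookup %in% names(raw)]
  trees <- raw[, unname(present), drop = FALSE]
  names(trees) <- names(present)
  required <- c("id", "x", "y", "species", "dbh")
  missing_cols <- setdiff(required, names(trees))
  if (length(missing_cols) > 0) {
    abort(sprintf("File %s lacks required column(s): %s.", path,
                  paste(missing_cols, collapse = ", ")))
  }
  for (col in intersect(c("x", "y", "dbh", "height", "crown_base_height",
                          "crown_consumption"), names(trees))) {
    v <- trees[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0) {
        abort(sprintf("Non-numeric value in column `%s` at data row %d.",
                      col, bad[1]))
      }
      trees[[col]] <- num
    }
  }
  if (!is.null(min_dbh)) trees <- trees[trees$dbh >= min_dbh, , drop = FALSE]
  if (drop_outside) {
    outside <- !in_window(trees$x, trees$y, window)
    if (any(outside)) {
      warn(sprintf("Dropping %d row(s) outside the window.", sum(outside)))
      trees <- trees[!outside, , drop = FALSE]
    }
  }
  stem_map(trees, window, label = basename(path))
}

#' Write a stem map to delimited text
#'
#' Emits the same dialect [read_stem_map()] consumes, so a write-then-read
#' round trip reproduces all fields.
#'
#' @param map A [stem_map()].
#' @param path Output path; ".csv" writes comma-delimited, anything else tab.
#' @param window_config Optional path for a YAML window sidecar
#'   (keys `x_min`, `x_max`, `y_min`, `y_max`).
#' @return `path`, invisibly.
#' @export
write_stem_map <- function(map, path, window_config = NULL) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(as_tibble(map), path, delim = delim, progress = FALSE)
  if (!is.null(window_config)) {
    w <- map_window(map)
    yaml::write_yaml(list(x_min = w$x_min, x_max = w$x_max,
                          y_min = w$y_min, y_max = w$y_max), window_config)
  }
  invisible(path)
}

#' Read a plot window from a YAML key-value file
#'
#' @param path YAML file with keys `x_min`, `x_max`, `y_min`, `y_max`.
#' @return A [plot_window()].
#' @export
read_window_config <- function(path) {
  as_plot_window(yaml::read_yaml(path))
}

#' Attach externally simulated crown consumption by tree id
#'
#' Joins a two-column table (`id`, `crown_consumption`) -- e.g. per-tree
#' output from an external fire simulation -- onto a stem map.
#'
#' @param map A [stem_map()].
#' @param consumption A data frame with columns `id` and `crown_consumption`
#'   (fractions in \[0, 1\]), or a path to a delimited file of the same.
#' @return The stem map with a `crown_consumption` column.
#' @export
attach_consumption <- function(map, consumption) {
  if (is.character(consumption)) {
    delim <- if (grepl("\\.csv$", consumption, ignore.case = TRUE)) "," else "\t"
    consumption <- readr::read_delim(consumption, delim = delim,
                                     show_col_types = FALSE, progress = FALSE)
  }
  consumption <- as_tibble(consumption)[, c("id", "crown_consumption")]
  missing_ids <- setdiff(map$id, consumption$id)
  if (length(missing_ids) > 0) {
    abort(sprintf("Consumption table lacks %d tree id(s), e.g.: %s.",
                  length(missing_ids),
                  paste(head(missing_ids, 5), collapse = ", ")))
  }
  joined <- dplyr::left_join(
    dplyr::select(as_tibble(map), -dplyr::any_of("crown_consumption")),
    consumption, by = "id"
  )
  stem_map(joined, map_window(map), map_label(map))
}

#' Aspatial stand-structure summary
#'
#' Computes the standard inventory summaries of a stem map: stem density
#' (trees/ha), basal area (m^2/ha), quadratic mean diameter (cm) and canopy
#' base height expressed as the tenth percentile of tree crown base heights
#' (m; linear-interpolation quantile).
#'
#' @param map A [stem_map()] with at least one tree.
#' @return A one-row tibble with columns `n`, `tph`, `ba`, `qmd`, `cbh10`
#'   (`cbh10` is `NA` when no tree carries a crown base height).
#' @examples
#' m <- stem_map(data.frame(id = 1, x = 50, y = 50, species = "ABCO", dbh = 40),
#'               plot_window(0, 100, 0, 100))
#' summarize_structure(m) # tph 1, ba ~0.1257, qmd 40
#' @export
summarize_structure <- function(map) {
  if (nrow(map) == 0) abort("Cannot summarize an empty stem map.")
  area_ha <- map_window(map)$area_ha
  n <- nrow(map)
  ba <- sum(pi * (map$dbh / 200)^2) / area_ha
  qmd <- sqrt(sum(map$dbh^2) / n)
  cbh10 <- NA_real_
  if ("crown_base_height" %in% names(map) &&
      any(is.finite(map$crown_base_height))) {
    cbh10 <- unname(quantile(map$crown_base_height, 0.10, na.rm = TRUE,
                             type = 7))
  }
  tibble(n = n, tph = n / area_ha, ba = ba, qmd = qmd, cbh10 = cbh10)
}
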