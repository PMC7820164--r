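# Plain-text serializers: every result type round-trips through delimited
# text so runs can be diffed and post-processed without R objects.

#' Write a correlation function to delimited text
#'
#' Tab-separated `r`, `value` preceded by `#`-prefixed metadata lines
#' (kind, ring width, edge correction, point count).
#'
#' @param x An `fcf`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcf <- function(x, path) {
  breaks <- attr(x, "breaks")
  hdr <- c(
    sprintf("# kind: %s", fcf_kind(x) %||% "unknown"),
    sprintf("# ring: %g", if (length(breaks) > 1) breaks[2] - breaks[1] else NA),
    sprintf("# correction: %s", attr(x, "correction")),
    sprintf("# n: %d", attr(x, "n"))
  )
  writeLines(c(hdr, "r\tvalue",
               sprintf("%g\t%.10g", x$r, x$value)), path)
  invisible(path)
}

#' Read a correlation function written by [write_fcf()]
#'
#' @param path File path.
#' @return A tibble with columns `r`, `value` and the metadata as
#'   attributes.
#' @export
read_fcf <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- readr::read_tsv(I(lines[!grepl("^#", lines)]),
                          show_col_types = FALSE, progress = FALSE)
  out <- as_tibble(body)
  for (m in meta) {
    kv <- strsplit(sub("^# ", "", m), ": ")[[1]]
    attr(out, kv[1]) <- utils::type.convert(kv[2], as.is = TRUE)
  }
  class(out) <- c("fcf", class(out))
  out
}

#' Write an envelope result to delimited text
#'
#' Tab-separated `r`, `observed`, `null_mean`, `lo`, `hi`, `z` with a
#' one-line verdict record (statistic kind, significance, r-averaged z,
#' critical value, simulation count) in the header.
#'
#' @param x An `fs_envelope`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(x, path) {
  verdict <- sprintf(
    "# verdict: kind=%s significant=%s r_averaged_z=%.6g crit=%.6g n_sim=%d alpha=%g",
    attr(x, "kind") %||% "?", attr(x, "significant"),
    attr(x, "r_averaged_z"), attr(x, "crit"), attr(x, "n_sim"),
    attr(x, "alpha"))
  body <- sprintf("%g\t%.10g\t%.10g\t%.10g\t%.10g\t%.10g",
                  x$r, x$observed, x$null_mean, x$lo, x$hi, x$z)
  writeLines(c(verdict, "r\tobserved\tnull_mean\tlo\thi\tz", body), path)
  invisible(path)
}

#' Serialize a scenario report to its output directory
#'
#' Writes the classified stem map, structure summaries, every envelope,
#' group tables, the flow matrix (wide and long edge-list form), the
#' machine-readable JSON summary, and a run log (package version and
#' per-stage seeds). The summary carries no timestamps, so identical
#' configurations and seeds produce byte-identical summaries.
#'
#' @param report A `scenario_report` whose config has a non-`NULL`
#'   `out_dir`.
#' @return The output directory, invisibly.
#' @export
write_scenario_report <- function(report) {
  dir <- report$config$out_dir
  if (is.null(dir)) abort("Report config has no out_dir.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)

  write_stem_map(report$map, p("stem_map.tsv"),
                 window_config = p("window.yml"))
  readr::write_tsv(report$structure, p("structure.tsv"), progress = FALSE)
  for (nm in names(report$envelopes)) {
    write_envelope(report$envelopes[[nm]], p(sprintf("envelope_%s.tsv", nm)))
  }
  readr::write_tsv(report$groups_pre$groups, p("groups_prefire.tsv"),
                   progress = FALSE)
  if (!is.null(report$groups_post)) {
    readr::write_tsv(report$groups_post$groups, p("groups_postfire.tsv"),
                     progress = FALSE)
  }
  flow_wide <- as.data.frame(report$flow$matrix)
  flow_wide <- cbind(from_class = rownames(report$flow$matrix), flow_wide)
  readr::write_tsv(as_tibble(flow_wide), p("group_flow_matrix.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$flow$flows, p("group_flow_edges.tsv"),
                   progress = FALSE)

  summary_list <- list(
    label = report$config$label,
    n_trees = nrow(report$map),
    n_killed = sum(report$map$status == "killed"),
    statistics = report$summary
  )
  jsonlite::write_json(summary_list, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  log_lines <- c(
    sprintf("firestem version: %s",
            as.character(utils::packageVersion("firestem"))),
    sprintf("R version: %s", R.version.string),
    sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("master seed: %s", report$config$master_seed),
    sprintf("stage seeds: %s", paste(report$seeds, collapse = ", "))
  )
  writeLines(log_lines, p("run_log.txt"))
  invisible(dir)
}
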