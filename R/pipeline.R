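#' Scenario configuration
#'
#' Bundles everything one end-to-end analysis needs: the input stand (a
#' stem-map file, a synthetic preset, or an in-memory [stem_map()]), the
#' fire (surrogate config or an external per-tree consumption table), the
#' mortality coefficients, and the analysis settings. All randomness in a
#' run derives deterministically from `master_seed` via a per-stage counter
#' (stage 1 stand generation, 2 fire, 3 prefire pattern null, 4/5 mark
#' nulls, 6 postfire pattern null, 7 labeling null), so any stage can be
#' re-run in isolation.
#'
#' @param input One of: a [stem_map()]; a list
#'   `list(preset = "historical"|"contemporary", window = )`; or a list
#'   `list(path = , window = , columns = , min_dbh = )` for a stem-map
#'   file.
#' @param fire A [surrogate_fire_config()] (default [preset_fire_config()]),
#'   or a path/data frame of per-tree consumption (`id`,
#'   `crown_consumption`).
#' @param coeffs A [mortality_coefficients()] table or a file path
#'   (default [default_mortality_coefficients()]).
#' @param r_max,ring,bandwidth,n_sim,alpha,linkage Analysis settings
#'   (defaults 15 m, 1 m, 20 m, 399 simulations, 0.05, 6 m).
#' @param threshold Mortality probability threshold (default 0.5).
#' @param out_dir Output directory for serialized results, or `NULL` to
#'   keep results in memory only.
#' @param master_seed Integer master seed (default 1).
#' @param label Scenario label used in reports.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(input, fire = preset_fire_config(),
                            coeffs = default_mortality_coefficients(),
                            r_max = 15, ring = 1, bandwidth = 20,
                            n_sim = 399, alpha = 0.05, linkage = 6,
                            threshold = 0.5, out_dir = NULL,
                            master_seed = 1, label = NULL) {
  if (is.character(coeffs)) coeffs <- read_mortality_coefficients(coeffs)
  structure(
    list(input = input, fire = fire, coeffs = coeffs, r_max = r_max,
         ring = ring, bandwidth = bandwidth, n_sim = as.integer(n_sim),
         alpha = alpha, linkage = linkage, threshold = threshold,
         out_dir = out_dir, master_seed = master_seed, label = label),
    class = "scenario_config"
  )
}

#' Read a scenario configuration from a YAML file
#'
#' Key-value layout mirroring [scenario_config()]: an `input` block with
#' either `preset` + `window` (list of x_min/x_max/y_min/y_max) or `path` +
#' `window`; optional `fire` block (surrogate parameters); optional
#' `coeffs` path; analysis keys at the top level.
#'
#' @param path YAML file path.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- y$input
  if (!is.null(input$window)) input$window <- as_plot_window(input$window)
  fire <- if (is.null(y$fire)) preset_fire_config() else {
    do.call(surrogate_fire_config, y$fire)
  }
  coeffs <- if (is.null(y$coeffs)) default_mortality_coefficients() else y$coeffs
  args <- y[intersect(names(y), c("r_max", "ring", "bandwidth", "n_sim",
                                  "alpha", "linkage", "threshold",
                                  "out_dir", "master_seed", "label"))]
  do.call(scenario_config, c(list(input = input, fire = fire,
                                  coeffs = coeffs), args))
}

load_scenario_input <- function(config, seed) {
  inp <- config$input
  if (inherits(inp, "stem_map")) return(inp)
  if (is.list(inp) && !is.null(inp$preset)) {
    fc <- preset_forest_config(inp$preset, as_plot_window(inp$window),
                               seed = seed)
    return(generate_forest(fc, label = config$label %||% inp$preset))
  }
  if (is.list(inp) && !is.null(inp$path)) {
    return(read_stem_map(inp$path, as_plot_window(inp$window),
                         columns = inp$columns, min_dbh = inp$min_dbh))
  }
  abort("Unrecognized scenario input; see ?scenario_config.")
}

#' Run a full fire/pattern scenario
#'
#' Executes the whole chain on one stand: load or generate the stem map;
#' simulate (or join) per-tree crown consumption; classify fire-killed
#' trees; test the prefire pattern (`g` against an inhomogeneous Poisson
#' null) and prefire size structure (`k_mark`, `gamma_mark` against random
#' marking); test the survivor pattern (`g` on survivors); test mortality
#' clustering and density dependence (`g_cluster`, `g_densdep` against
#' random labeling); identify pre- and postfire tree groups, their flow
#' matrix, and the pre/post group-size comparison. When `out_dir` is set,
#' all results are serialized as delimited text plus a JSON summary and a
#' run log.
#'
#' @param config A [scenario_config()].
#' @return A `scenario_report` list: `map` (classified stem map),
#'   `structure` (pre/post [summarize_structure()]), `envelopes` (named
#'   list of [global_envelope()] results), `groups_pre`, `groups_post`,
#'   `flow`, `group_comparison`, `summary` (one row per statistic), and
#'   `seeds`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  seeds <- vapply(1:7, function(k) derive_seed(config$master_seed, k),
                  integer(1))
  stage <- "input"
  report <- list(config = config, seeds = seeds)
  tryCatch({
    map <- load_scenario_input(config, seeds[1])

    stage <- "fire"
    map <- if (inherits(config$fire, "surrogate_fire_config")) {
      fire_cfg <- config$fire
      fire_cfg$seed <- fire_cfg$seed %||% seeds[2]
      surrogate_consumption(map, fire_cfg)
    } else {
      attach_consumption(map, config$fire)
    }

    stage <- "mortality"
    map <- classify_mortality(map, config$coeffs, config$threshold)
    report$map <- map
    survivors <- restamp(map[map$status == "alive", , drop = FALSE], map)
    report$structure <- dplyr::bind_rows(
      dplyr::mutate(summarize_structure(map), phase = "prefire"),
      dplyr::mutate(summarize_structure(survivors), phase = "postfire")
    )

    stage <- "prefire patterns"
    env <- list()
    env$g_all <- envelope_test(map, "g", n_sim = config$n_sim,
                               alpha = config$alpha, r_max = config$r_max,
                               ring = config$ring, seed = seeds[3],
                               bandwidth = config$bandwidth)
    env$k_dbh <- envelope_test(map, "k_mark", n_sim = config$n_sim,
                               alpha = config$alpha, r_max = config$r_max,
                               ring = config$ring, seed = seeds[4])
    env$gamma_dbh <- envelope_test(map, "gamma_mark", n_sim = config$n_sim,
                                   alpha = config$alpha, r_max = config$r_max,
                                   ring = config$ring, seed = seeds[5])

    stage <- "postfire pattern"
    env$g_alive <- envelope_test(survivors, "g", n_sim = config$n_sim,
                                 alpha = config$alpha, r_max = config$r_max,
                                 ring = config$ring, seed = seeds[6],
                                 bandwidth = config$bandwidth)

    stage <- "mortality patterns"
    mort <- mortality_envelopes(map, n_sim = config$n_sim,
                                alpha = config$alpha, r_max = config$r_max,
                                ring = config$ring, seed = seeds[7])
    env$g_cluster <- mort$g_cluster
    env$g_densdep <- mort$g_densdep
    report$envelopes <- env

    stage <- "groups"
    report$groups_pre <- identify_groups(map, config$linkage)
    report$groups_post <- if (nrow(survivors) > 0) {
      identify_groups(survivors, config$linkage)
    } else NULL
    report$flow <- group_flow(report$groups_pre, map, config$linkage)
    report$group_comparison <- if (!is.null(report$groups_post) &&
                                   nrow(report$groups_post$groups) >= 2) {
      compare_group_sizes(group_sizes(report$groups_pre),
                          group_sizes(report$groups_post))
    } else NULL

    report$summary <- dplyr::bind_rows(lapply(names(env), function(nm) {
      dplyr::mutate(glance(env[[nm]]), statistic = nm, .before = 1)
    }))
    class(report) <- "scenario_report"

    stage <- "output"
    if (!is.null(config$out_dir)) write_scenario_report(report)
    report
  }, error = function(e) {
    abort(sprintf("Scenario failed at stage '%s': %s", stage,
                  conditionMessage(e)), parent = e)
  })
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> %s: %d trees, %d killed (%.0f%%)\n",
              x$config$label %||% "scenario", nrow(x$map),
              sum(x$map$status == "killed"),
              100 * mean(x$map$status == "killed")))
  print(x$summary)
  invisible(x)
}

#' Compare two scenario reports
#'
#' Side-by-side comparison of the pattern statistics (r-averaged z and
#' significance per statistic; statistics present in only one report keep
#' an explicit `NA` gap), the group-size distributions (pre- and postfire
#' comparisons between the scenarios, with tests), and the flow-matrix
#' margins.
#'
#' @param report_a,report_b `scenario_report`s run with identical analysis
#'   settings (checked; mismatches are an error).
#' @return A `scenario_comparison` list with tibbles `statistics`,
#'   `groups`, and the two flow margins.
#' @export
compare_scenarios <- function(report_a, report_b) {
  for (key in c("r_max", "ring", "bandwidth", "n_sim", "alpha", "linkage")) {
    if (!identical(report_a$config[[key]], report_b$config[[key]])) {
      abort(sprintf("Analysis settings differ (`%s`); reports not comparable.",
                    key))
    }
  }
  sum_a <- dplyr::select(report_a$summary, "statistic",
                         z_a = "r_averaged_z", sig_a = "significant")
  sum_b <- dplyr::select(report_b$summary, "statistic",
                         z_b = "r_averaged_z", sig_b = "significant")
  stats_tbl <- dplyr::full_join(sum_a, sum_b, by = "statistic")

  grp <- dplyr::bind_rows(
    group_phase_comparison(report_a, report_b, "pre"),
    group_phase_comparison(report_a, report_b, "post")
  )
  structure(
    list(statistics = stats_tbl, groups = grp,
         flow_a = margin_tbl(report_a$flow), flow_b = margin_tbl(report_b$flow)),
    class = "scenario_comparison"
  )
}

group_phase_comparison <- function(a, b, phase) {
  ga <- if (phase == "pre") a$groups_pre else a$groups_post
  gb <- if (phase == "pre") b$groups_pre else b$groups_post
  if (is.null(ga) || is.null(gb)) {
    return(tibble(phase = phase, median_a = NA_real_, median_b = NA_real_,
                  cv_a = NA_real_, cv_b = NA_real_, wilcoxon_p = NA_real_,
                  slrt_p = NA_real_))
  }
  cmp <- compare_group_sizes(group_sizes(ga), group_sizes(gb))
  g <- glance(cmp)
  tibble(phase = phase, median_a = g$median_a, median_b = g$median_b,
         cv_a = g$cv_a, cv_b = g$cv_b, wilcoxon_p = g$wilcoxon_p,
         slrt_p = g$slrt_p)
}

margin_tbl <- function(flow) {
  if (is.null(flow)) return(NULL)
  m <- flow$matrix
  tibble(class = rownames(m), prefire_trees = rowSums(m),
         killed = m[, "killed"])
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("<scenario_comparison>\n")
  print(x$statistics)
  print(x$groups)
  invisible(x)
}
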