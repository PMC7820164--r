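#' Configuration for the synthetic stand generator
#'
#' Describes a two-layer generative model for stem maps:
#' a Thomas cluster process (Poisson parents of intensity `kappa`, each with
#' a Poisson(`mu`) brood of offspring displaced by isotropic Gaussian noise
#' with scale `sigma`) for the small/medium cohort, superposed with
#' `n_large` "overstory" trees placed by dart throwing under a hard-core
#' minimum spacing `r_inhibit`. Offspring diameters combine a cluster-level
#' effect with idiosyncratic lognormal noise: `mark_coupling` is the
#' fraction of log-dbh variance carried by the cluster, so trees within a
#' cluster are similar in size when it is near 1 and marks are independent
#' of location when it is 0.
#'
#' @param window A [plot_window()].
#' @param kappa Parent intensity (parents per m^2), > 0.
#' @param sigma Gaussian offspring dispersal scale (m), > 0.
#' @param mu Mean offspring per parent, >= 0.
#' @param n_large Number of hard-core large trees (>= 0).
#' @param r_inhibit Minimum spacing among large trees (m), >= 0.
#' @param dbh_small,dbh_large Length-2 numerics `c(median_cm, log_sd)` for
#'   the lognormal diameters of the clustered and large layers.
#' @param mark_coupling Fraction in \[0, 1\] of offspring log-dbh variance
#'   explained by the cluster-level effect.
#' @param species_probs Named probability vector for species codes.
#' @param parent_clustering Optional second clustering level: a list
#'   `list(kappa_g, mu_g, sigma_g)` under which cluster parents are
#'   themselves a Thomas process (grandparent intensity `kappa_g` per m^2,
#'   `Poisson(mu_g)` parents per grandparent, Gaussian dispersal
#'   `sigma_g` m) instead of Poisson with intensity `kappa`. The realized
#'   parent intensity is then `kappa_g * mu_g` (`kappa` is ignored). This
#'   produces aggregation both at the clump scale (`sigma`) and at the
#'   clump-neighborhood scale (`sigma_g`), as in stands whose tree groups
#'   are themselves gathered into denser neighborhoods.
#' @param cbh_scale,cbh_log_sd Crown-base-height model: a tree of dbh d gets
#'   `cbh_scale * (d/30)^0.8 * exp(N(0, cbh_log_sd))` meters, capped at 90%
#'   of its height.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A `forest_config` list.
#' @seealso [generate_forest()], [preset_forest_config()]
#' @export
forest_config <- function(window,
                          kappa, sigma, mu,
                          n_large = 0, r_inhibit = 0,
                          dbh_small = c(25, 0.4),
                          dbh_large = c(80, 0.25),
                          mark_coupling = 0.5,
                          species_probs = c(ABCO = 0.35, PILA = 0.25,
                                            CADE = 0.20, PIPO = 0.15,
                                            PIJE = 0.05),
                          parent_clustering = NULL,
                          cbh_scale = 2.5, cbh_log_sd = 0.35,
                          seed = NULL) {
  window <- as_plot_window(window)
  assert_number(kappa, "kappa", lower = 1e-12)
  assert_number(sigma, "sigma", lower = 1e-12)
  assert_number(mu, "mu", lower = 0)
  assert_number(n_large, "n_large", lower = 0)
  assert_number(r_inhibit, "r_inhibit", lower = 0)
  assert_number(mark_coupling, "mark_coupling", lower = 0, upper = 1)
  stopifnot(length(dbh_small) == 2, length(dbh_large) == 2)
  if (abs(sum(species_probs) - 1) > 1e-8) {
    species_probs <- species_probs / sum(species_probs)
  }
  structure(
    list(window = window, kappa = kappa, sigma = sigma, mu = mu,
         n_large = as.integer(n_large), r_inhibit = r_inhibit,
         dbh_small = dbh_small, dbh_large = dbh_large,
         mark_coupling = mark_coupling, species_probs = species_probs,
         parent_clustering = parent_clustering,
         cbh_scale = cbh_scale, cbh_log_sd = cbh_log_sd, seed = seed),
    class = "forest_config"
  )
}

#' Era presets for the synthetic stand generator
#'
#' Two calibrated parameterizations spanning the structural contrast between
#' frequent-fire-era stands and long-unburned contemporary stands in dry
#' mixed-conifer forest:
#' * `"historical"`: ~350 trees/ha, QMD ~45 cm, small trees in tight
#'   clumps (`sigma` 2 m) that are themselves gathered into clump
#'   neighborhoods (`sigma_g` 12 m), strong size segregation
#'   (`mark_coupling` 0.8), tall crown bases (tenth percentile ~1.4 m),
#'   sparse large trees under an 8 m hard core.
#' * `"contemporary"`: ~760 trees/ha, QMD ~34 cm, weakly clustered
#'   (`sigma` 7 m), intermixed sizes (`mark_coupling` 0.3), low crown bases
#'   (tenth percentile ~0.7 m).
#'
#' @param era `"historical"` or `"contemporary"`.
#' @param window A [plot_window()]; preset intensities are per unit area, so
#'   any window size works.
#' @param seed Optional integer seed stored in the config.
#' @return A [forest_config()].
#' @export
preset_forest_config <- function(era = c("historical", "contemporary"),
                                 window, seed = NULL) {
  era <- match.arg(era)
  window <- as_plot_window(window)
  area <- window_area_m2(window)
  if (era == "historical") {
    forest_config(
      window = window,
      kappa = 0.004, sigma = 2, mu = 7.5,
      n_large = round(area * 0.00488), r_inhibit = 8,
      dbh_small = c(28, 0.45), dbh_large = c(80, 0.25),
      mark_coupling = 0.8,
      parent_clustering = list(kappa_g = 0.0004, mu_g = 10, sigma_g = 10),
      cbh_scale = 2.7, cbh_log_sd = 0.35,
      seed = seed
    )
  } else {
    forest_config(
      window = window,
      kappa = 0.0074, sigma = 6, mu = 9.6,
      n_large = round(area * 0.00676), r_inhibit = 6,
      dbh_small = c(24, 0.35), dbh_large = c(70, 0.25),
      mark_coupling = 0.3,
      cbh_scale = 1.55, cbh_log_sd = 0.35,
      seed = seed
    )
  }
}

#' Generate a synthetic stem map
#'
#' Draws one realization of the stand model described in
#' [forest_config()]. Parents are simulated in a buffer of 4 `sigma`
#' (plus 4 `sigma_g` for the two-level variant) beyond the window so
#' clusters straddling the boundary are not thinned; offspring falling
#' outside the window are discarded. With `parent_clustering = NULL` the
#' clustered layer restricted to the window is a stationary Thomas
#' process with closed-form pair correlation
#' g(r) = 1 + exp(-r^2 / (4 sigma^2)) / (4 pi sigma^2 kappa); with a
#' second level the pattern is aggregated at both the `sigma` and
#' `sigma_g` scales.
#'
#' @param config A [forest_config()].
#' @param label Label stored on the returned map; defaults to none.
#' @return A [stem_map()] with columns `id`, `x`, `y`, `species`, `dbh`,
#'   `height`, `crown_base_height`, and a logical `large` flag for the
#'   hard-core layer.
#' @export
generate_forest <- function(config, label = NULL) {
  stopifnot(inherits(config, "forest_config"))
  with_seed(config$seed, {
    w <- config$window
    buf <- 4 * config$sigma

    # Thomas cluster layer: parents on the buffered window, either
    # Poisson (single-level) or themselves Thomas-clustered (two-level).
    pc <- config$parent_clustering
    if (is.null(pc)) {
      bx <- w$width + 2 * buf
      by <- w$height + 2 * buf
      n_parents <- rpois(1, config$kappa * bx * by)
      px <- runif(n_parents, w$x_min - buf, w$x_max + buf)
      py <- runif(n_parents, w$y_min - buf, w$y_max + buf)
    } else {
      gbuf <- buf + 4 * pc$sigma_g
      bx <- w$width + 2 * gbuf
      by <- w$height + 2 * gbuf
      n_g <- rpois(1, pc$kappa_g * bx * by)
      gx <- runif(n_g, w$x_min - gbuf, w$x_max + gbuf)
      gy <- runif(n_g, w$y_min - gbuf, w$y_max + gbuf)
      gsize <- if (n_g > 0) rpois(n_g, pc$mu_g) else integer(0)
      g_of <- rep.int(seq_len(n_g), gsize)
      px <- rnorm(length(g_of), gx[g_of], pc$sigma_g)
      py <- rnorm(length(g_of), gy[g_of], pc$sigma_g)
      inside <- px >= w$x_min - buf & px <= w$x_max + buf &
        py >= w$y_min - buf & py <= w$y_max + buf
      px <- px[inside]; py <- py[inside]
      n_parents <- length(px)
    }
    brood <- if (n_parents > 0) rpois(n_parents, config$mu) else integer(0)
    parent_effect <- rnorm(n_parents)

    parent_of <- rep.int(seq_len(n_parents), brood)
    ox <- rnorm(length(parent_of), px[parent_of], config$sigma)
    oy <- rnorm(length(parent_of), py[parent_of], config$sigma)
    keep <- in_window(ox, oy, w)
    ox <- ox[keep]; oy <- oy[keep]; parent_of <- parent_of[keep]

    s <- config$dbh_small[2]
    cc <- config$mark_coupling
    log_d <- log(config$dbh_small[1]) +
      s * (sqrt(cc) * parent_effect[parent_of] +
             sqrt(1 - cc) * rnorm(length(parent_of)))
    small <- tibble(x = ox, y = oy, dbh = exp(log_d), large = FALSE)

    # Hard-core large-tree layer by sequential rejection (dart throwing).
    lx <- numeric(0); ly <- numeric(0)
    if (config$n_large > 0) {
      attempts <- 0L
      while (length(lx) < config$n_large) {
        attempts <- attempts + 1L
        if (attempts > 10000L) {
          abort(sprintf(
            "Could not place %d large trees at %g m spacing in %d attempts; packing infeasible.",
            config$n_large, config$r_inhibit, 10000L))
        }
        cx <- runif(1, w$x_min, w$x_max)
        cy <- runif(1, w$y_min, w$y_max)
        if (length(lx) == 0 ||
            min((lx - cx)^2 + (ly - cy)^2) >= config$r_inhibit^2) {
          lx <- c(lx, cx); ly <- c(ly, cy)
        }
      }
    }
    big <- tibble(
      x = lx, y = ly,
      dbh = exp(log(config$dbh_large[1]) +
                  config$dbh_large[2] * rnorm(length(lx))),
      large = TRUE
    )

    trees <- dplyr::bind_rows(small, big)
    n <- nrow(trees)
    species <- if (n > 0) {
      sample(names(config$species_probs), n, replace = TRUE,
             prob = config$species_probs)
    } else character(0)
    # Height allometry (asymptotic in dbh) and crown base heights.
    height <- 1.37 + 30 * (1 - exp(-0.03 * trees$dbh))^1.2
    cbh <- config$cbh_scale * (trees$dbh / 30)^0.8 *
      exp(rnorm(n, 0, config$cbh_log_sd))
    cbh <- pmin(cbh, 0.9 * height)
    trees <- tibble(
      id = sprintf("t%05d", seq_len(n)),
      x = trees$x, y = trees$y,
      species = species, dbh = trees$dbh,
      height = height, crown_base_height = cbh,
      large = trees$large
    )
    stem_map(trees, w, label = label)
  })
}
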