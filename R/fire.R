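#' Species-specific logistic mortality coefficients
#'
#' Mortality likelihood is modeled as
#' `p = logistic(b0 + b1*C + b2*C^2 + b3*dbh + b4*C*dbh)` where `C` is
#' crown consumption **in percent** (0-100) -- crown consumption substitutes
#' for crown volume scorched in scorch-based mortality regressions -- and
#' dbh is in cm. A coefficient table holds one row per species plus an
#' optional `".default"` row used for species without their own row.
#'
#' The table shipped by [default_mortality_coefficients()] is illustrative
#' only (plausible magnitudes: mortality rises with consumption, falls with
#' dbh); it is **not** a published regression. Supply your own table for any
#' real analysis, e.g. via [read_mortality_coefficients()].
#'
#' @param species Character vector of species codes (`".default"` allowed).
#' @param b0,b1,b2,b3,b4 Numeric coefficient vectors recycled to
#'   `length(species)`: intercept, consumption (per percent), consumption
#'   squared, dbh (per cm), consumption x dbh.
#' @return A tibble of class `mortality_coefficients`.
#' @export
mortality_coefficients <- function(species, b0 = 0, b1 = 0, b2 = 0,
                                   b3 = 0, b4 = 0) {
  out <- tibble(species = as.character(species), b0 = b0, b1 = b1,
                b2 = b2, b3 = b3, b4 = b4)
  if (anyDuplicated(out$species)) abort("Duplicate species in coefficient table.")
  class(out) <- c("mortality_coefficients", class(out))
  out
}

#' @rdname mortality_coefficients
#' @export
default_mortality_coefficients <- function() {
  mortality_coefficients(
    species = c("ABCO", "CADE", "PILA", "PIPO", "PIJE", ".default"),
    b0 = c(-1.2, -1.4, -1.6, -2.0, -2.0, -1.5),
    b1 = c(0.075, 0.072, 0.070, 0.066, 0.066, 0.070),
    b2 = 0,
    b3 = c(-0.042, -0.040, -0.048, -0.050, -0.050, -0.045),
    b4 = 0
  )
}

#' Read a mortality coefficient table from delimited text
#'
#' Expects columns `species`, `b0`, `b1`, `b2`, `b3`, `b4`; consumption
#' coefficients must be on the percent (0-100) scale.
#'
#' @param path Delimited text file (".csv" comma, otherwise tab).
#' @return A [mortality_coefficients()] table.
#' @export
read_mortality_coefficients <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  mortality_coefficients(x$species, x$b0, x$b1, x$b2, x$b3, x$b4)
}

coef_rows_for <- function(species, coeffs) {
  idx <- match(species, coeffs$species)
  default_row <- match(".default", coeffs$species)
  missing <- is.na(idx)
  if (any(missing)) {
    if (is.na(default_row)) {
      abort(sprintf("No coefficient row (and no '.default') for species: %s.",
                    paste(unique(species[missing]), collapse = ", ")))
    }
    idx[missing] <- default_row
  }
  idx
}

#' Fire-caused mortality probability
#'
#' Evaluates the logistic mortality model for vectors of trees. Crown
#' consumption is supplied as a fraction in \[0, 1\] and internally rescaled
#' to percent to match the coefficient convention.
#'
#' @param dbh Diameter at breast height, cm.
#' @param species Species codes (matched against the coefficient table,
#'   falling back to its `".default"` row).
#' @param consumption Crown consumption fraction in \[0, 1\].
#' @param coeffs A [mortality_coefficients()] table.
#' @return Mortality probabilities in (0, 1).
#' @examples
#' # With b0 = -4, b1 = 0.08 the probability crosses 0.5 at 50% consumption.
#' co <- mortality_coefficients(".default", b0 = -4, b1 = 0.08)
#' mortality_probability(30, "PIPO", 0.5, co) # 0.5
#' @export
mortality_probability <- function(dbh, species, consumption, coeffs) {
  if (any(consumption < 0 | consumption > 1, na.rm = TRUE)) {
    abort("`consumption` must be a fraction in [0, 1].")
  }
  idx <- coef_rows_for(species, coeffs)
  C <- 100 * consumption
  eta <- coeffs$b0[idx] + coeffs$b1[idx] * C + coeffs$b2[idx] * C^2 +
    coeffs$b3[idx] * dbh + coeffs$b4[idx] * C * dbh
  plogis(eta)
}

#' Classify trees as fire-killed
#'
#' Applies the mortality model to every tree and labels those at or above
#' the probability threshold as `"killed"`, the rest `"alive"`. The default
#' threshold of 0.5 follows the convention that trees with mortality
#' likelihood >= 50% are designated fire-killed.
#'
#' @param map A [stem_map()] in which every tree has a `crown_consumption`.
#' @param coeffs A [mortality_coefficients()] table.
#' @param threshold Probability threshold in \[0, 1\].
#' @return The stem map with `mortality_p` and `status` columns.
#' @export
classify_mortality <- function(map, coeffs = default_mortality_coefficients(),
                               threshold = 0.5) {
  if (!"crown_consumption" %in% names(map) ||
      any(is.na(map$crown_consumption))) {
    missing_ids <- if ("crown_consumption" %in% names(map)) {
      map$id[is.na(map$crown_consumption)]
    } else map$id
    abort(sprintf("Missing crown consumption for %d tree(s), e.g.: %s.",
                  length(missing_ids),
                  paste(head(missing_ids, 5), collapse = ", ")))
  }
  p <- mortality_probability(map$dbh, map$species, map$crown_consumption,
                             coeffs)
  out <- dplyr::mutate(as_tibble(map), mortality_p = p,
                       status = ifelse(p >= threshold, "killed", "alive"))
  restamp(out, map)
}

#' Configuration for the surrogate crown-consumption model
#'
#' A desk-scale stand-in for a physics-based fire simulation: each tree's
#' crown consumption responds to its local competitive environment. With
#' `NBA` the summed basal area (m^2) of neighbors within `radius` and `CBH`
#' the tree's crown base height (m),
#' `consumption = logistic(a0 + a1*z(NBA) - a2*z(CBH) + N(0, noise_sd))`,
#' where `z()` standardizes within the map by default. Supplying fixed
#' `center`/`scale` pairs (named lists with elements `nba` and `cbh`)
#' replaces the within-map standardization with a fixed reference scale so
#' that consumption is comparable across stands of different density --
#' denser stands then burn harder, the mechanism by which crowded
#' contemporary stands sustain more crown fire than open historical ones.
#'
#' @param radius Neighborhood radius (m), > 0. Default 6 m, the same scale
#'   as tree-group linkage.
#' @param a0 Baseline logit.
#' @param a1 Gain on standardized neighborhood basal area, >= 0.
#' @param a2 Gain on standardized crown base height (entered negatively:
#'   lower crowns burn more), >= 0.
#' @param noise_sd Logit-scale noise standard deviation, >= 0.
#' @param center,scale Optional named lists `list(nba = , cbh = )` of fixed
#'   standardization constants; `NULL` standardizes within the map.
#' @param use_cbh Set `FALSE` to drop the crown-base-height term (for maps
#'   without crown base heights).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A `surrogate_fire_config` list.
#' @export
surrogate_fire_config <- function(radius = 6, a0 = 0, a1 = 1, a2 = 1,
                                  noise_sd = 0.25, center = NULL,
                                  scale = NULL, use_cbh = TRUE, seed = NULL) {
  assert_number(radius, "radius", lower = 1e-9)
  assert_number(a1, "a1", lower = 0)
  assert_number(a2, "a2", lower = 0)
  assert_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(radius = radius, a0 = a0, a1 = a1, a2 = a2, noise_sd = noise_sd,
         center = center, scale = scale, use_cbh = use_cbh, seed = seed),
    class = "surrogate_fire_config"
  )
}

#' Reference-scaled surrogate fire preset
#'
#' The surrogate configuration used by the scenario presets: fixed
#' standardization constants (taken from the historical-preset distribution
#' of neighborhood basal area and crown base height) so that the same fire
#' model applied to a denser, lower-crowned stand yields higher consumption.
#'
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param noise_sd Logit noise; default 0.25.
#' @return A [surrogate_fire_config()].
#' @export
preset_fire_config <- function(seed = NULL, noise_sd = 0.25) {
  surrogate_fire_config(
    radius = 6, a0 = -0.75, a1 = 1.1, a2 = 3.2, noise_sd = noise_sd,
    center = list(nba = 0.55, cbh = 3.0),
    scale = list(nba = 0.45, cbh = 1.6),
    seed = seed
  )
}

#' Simulate per-tree crown consumption
#'
#' Applies the surrogate fire model of [surrogate_fire_config()] to a stem
#' map and attaches a `crown_consumption` column (fraction in \[0, 1\]).
#'
#' @param map A [stem_map()]; needs `crown_base_height` unless
#'   `config$use_cbh` is `FALSE`.
#' @param config A [surrogate_fire_config()].
#' @return The stem map with `nba` (neighborhood basal area, m^2) and
#'   `crown_consumption` columns.
#' @export
surrogate_consumption <- function(map, config) {
  stopifnot(inherits(config, "surrogate_fire_config"))
  w <- map_window(map)
  if (config$radius > min(w$width, w$height)) {
    warn("Neighborhood radius exceeds the shorter window side; edge bias likely.")
  }
  n <- nrow(map)
  ba <- pi * (map$dbh / 200)^2
  nba <- neighborhood_sum(map$x, map$y, ba, config$radius)

  z <- function(v, which) {
    ctr <- config$center[[which]] %||% mean(v)
    scl <- config$scale[[which]] %||% sd(v)
    if (!is.finite(scl) || scl <= 0) scl <- 1
    (v - ctr) / scl
  }
  eta <- config$a0 + config$a1 * z(nba, "nba")
  if (config$use_cbh) {
    if (!"crown_base_height" %in% names(map) ||
        any(!is.finite(map$crown_base_height))) {
      abort("Map lacks crown_base_height; set use_cbh = FALSE to drop that term.")
    }
    eta <- eta - config$a2 * z(map$crown_base_height, "cbh")
  }
  noise <- if (config$noise_sd > 0) {
    with_seed(config$seed, rnorm(n, 0, config$noise_sd))
  } else rep(0, n)
  consumption <- pmin(1, pmax(0, plogis(eta + noise)))
  out <- dplyr::mutate(as_tibble(map), nba = nba,
                       crown_consumption = consumption)
  restamp(out, map)
}

# Sum of `value` over neighbors strictly within `radius` (self excluded),
# computed in row blocks to bound memory.
neighborhood_sum <- function(x, y, value, radius) {
  n <- length(x)
  out <- numeric(n)
  block <- 512L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    hit <- d2 <= radius^2
    hit[cbind(seq_along(idx), idx)] <- FALSE
    out[idx] <- as.vector(hit %*% value)
  }
  out
}
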