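#' The bundled 11-object stimulus catalog (synthetic reconstruction)
#'
#' The original stimulus dimensions are not redistributed with this package;
#' this catalog is a synthetic stand-in constructed, by root-finding on the
#' analytic centroid formulas, to satisfy the design constraints of the four
#' experimental conditions:
#'
#' * Condition 1A: four solid frusta of equal volume differing in base,
#'   height and T/B ratio, with widely spread centroids and critical angles.
#' * Condition 1B: three hollow (thin-shell) objects sharing base size and
#'   T/B ratio, differing only in height.
#' * Condition 2A: two solids sharing base size and centroid height (hence
#'   critical angle) while differing in height and T/B ratio.
#' * Condition 2B: two solids sharing base size and height but differing in
#'   T/B ratio, with critical angles exactly 8.5 degrees apart.
#'
#' All dimensions are in dimensionless scene units.
#'
#' @return A validated 11-row catalog tibble.
#' @export
stimulus_catalog <- function() {
  # condition 1A: equal volume pi => h = 3 / (R^2 + R r + r^2)
  rim <- list(c(1.6, 0.2), c(1.1, 0.5), c(0.8, 0.65), c(0.55, 0.85))
  cat1a <- dplyr::bind_rows(lapply(seq_along(rim), function(i) {
    R <- rim[[i]][1]; r <- rim[[i]][2]
    h <- 3 / (R^2 + R * r + r^2)
    object_spec(paste0("obj1A_", i), R, r, h, "solid")
  }))

  # condition 1B: hollow cylinders, shared base and T/B ratio, heights vary
  cat1b <- dplyr::bind_rows(lapply(seq_along(c(1.5, 2.5, 3.5)), function(i) {
    object_spec(paste0("obj1B_", i), 1, 1, c(1.5, 2.5, 3.5)[i], "hollow_shell")
  }))

  # condition 2A: shared base (R = 1) and centroid (1.2), different h and T/B
  z_target <- 1.2
  h2 <- 3.2
  r2 <- stats::uniroot(
    function(r) solid_frustum_centroid(1, r, h2) - z_target,
    c(0, 1), tol = 1e-12
  )$root
  cat2a <- dplyr::bind_rows(
    object_spec("obj2A_1", 1, 1, 2 * z_target, "solid"),   # cylinder, z = h/2
    object_spec("obj2A_2", 1, r2, h2, "solid")
  )

  # condition 2B: shared base and height, critical angles 8.5 degrees apart
  h <- 3
  z_for <- function(theta_deg) 1 / tan(theta_deg * pi / 180)
  solve_r <- function(z) stats::uniroot(
    function(r) solid_frustum_centroid(1, r, h) - z, c(0, 1.5), tol = 1e-12
  )$root
  cat2b <- dplyr::bind_rows(
    object_spec("obj2B_1", 1, solve_r(z_for(40.0)), h, "solid"),  # less stable
    object_spec("obj2B_2", 1, solve_r(z_for(48.5)), h, "solid")
  )

  dplyr::bind_rows(cat1a, cat1b, cat2a, cat2b)
}

#' The bundled experiment designs
#'
#' Angle grids reproduce the published trial totals with the bundled
#' repetition counts: condition 1A runs 5-105 degrees in steps of 10
#' (11 angles x 4 objects x 2 sides x 2 reps = 176 trials), condition 1B
#' 20-80 in steps of 5 (13 x 3 x 2 x 2 = 156), and conditions 2A/2B use
#' 13-angle grids in steps of 5 with 3 repetitions (13 x 2 x 2 x 3 = 156),
#' centred on the objects' critical angles.
#'
#' @param catalog catalog whose object ids the designs reference; defaults
#'   to [stimulus_catalog()].
#' @return Named list of four [experiment_design()]s.
#' @export
experiment_designs <- function(catalog = stimulus_catalog()) {
  ids <- catalog$object_id
  list(
    exp1a = experiment_design("exp1a", 5, 105, 10,
                              grep("^obj1A", ids, value = TRUE),
                              repetitions = 2L),
    exp1b = experiment_design("exp1b", 20, 80, 5,
                              grep("^obj1B", ids, value = TRUE),
                              repetitions = 2L),
    exp2a = experiment_design("exp2a", 10, 70, 5,
                              grep("^obj2A", ids, value = TRUE),
                              repetitions = 3L),
    exp2b = experiment_design("exp2b", 15, 75, 5,
                              grep("^obj2B", ids, value = TRUE),
                              repetitions = 3L)
  )
}

#' Random solid-frustum catalogs
#'
#' Draws solid frusta with dimensions in the same range as the bundled
#' stimulus set: bottom radius uniform on \[0.6, 1.4\], T/B ratio uniform on
#' \[0, 1\], height uniform on \[1.2, 4\]. Passing a fixed `bottom_radius`
#' yields a shared-base family (as in most of the stimulus set), in which
#' the critical angle is controlled by the centroid alone — the family used
#' when probing how faithfully the centroid model tracks the physics.
#'
#' @param n number of objects.
#' @param seed integer seed.
#' @param bottom_radius optional fixed bottom radius; `NULL` draws it
#'   uniformly.
#' @return Catalog tibble with ids `rnd_01`, ...
#' @export
random_catalog <- function(n, seed, bottom_radius = NULL) {
  withr::with_seed(seed, {
    R <- if (is.null(bottom_radius)) stats::runif(n, 0.6, 1.4)
         else rep(bottom_radius, n)
    tb <- stats::runif(n, 0, 1)
    h <- stats::runif(n, 1.2, 4)
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      object_spec(sprintf("rnd_%02d", i), R[i], R[i] * tb[i], h[i], "solid")
    }))
  })
}
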