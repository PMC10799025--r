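#' Construct a stimulus object specification
#'
#' Stimuli are conical frusta of revolution standing upright on a table,
#' described in dimensionless scene units by their bottom radius, top radius
#' and height. Objects are either uniformly solid or thin hollow shells.
#' An optional `centroid_override` (vertical centroid height above the base)
#' takes precedence over the analytic centroid wherever the centroid is
#' needed, so externally tabulated feature values can be dropped in.
#'
#' @param object_id character scalar identifying the object.
#' @param bottom_radius bottom radius, > 0.
#' @param top_radius top radius, >= 0 (0 gives a cone).
#' @param height object height, > 0.
#' @param fill `"solid"` (uniform density) or `"hollow_shell"` (thin uniform
#'   lateral shell).
#' @param centroid_override optional vertical centroid height in (0, height).
#'
#' @return A one-row tibble with the spec columns; bind rows to form a
#'   catalog.
#' @export
object_spec <- function(object_id, bottom_radius, top_radius, height,
                        fill = c("solid", "hollow_shell"),
                        centroid_override = NA_real_) {
  fill <- match.arg(fill)
  stopifnot(is.character(object_id), length(object_id) == 1L)
  if (!is.numeric(bottom_radius) || bottom_radius <= 0) {
    stop("invalid object spec: bottom_radius must be > 0", call. = FALSE)
  }
  if (!is.numeric(top_radius) || top_radius < 0) {
    stop("invalid object spec: top_radius must be >= 0", call. = FALSE)
  }
  if (!is.numeric(height) || height <= 0) {
    stop("invalid object spec: height must be > 0", call. = FALSE)
  }
  if (!is.na(centroid_override) &&
      (centroid_override <= 0 || centroid_override >= height)) {
    stop("invalid object spec: centroid_override must lie strictly in (0, height)",
         call. = FALSE)
  }
  tibble::tibble(
    object_id = object_id,
    bottom_radius = as.numeric(bottom_radius),
    top_radius = as.numeric(top_radius),
    height = as.numeric(height),
    fill = fill,
    centroid_override = as.numeric(centroid_override)
  )
}

catalog_cols <- c("object_id", "bottom_radius", "top_radius", "height",
                  "fill", "centroid_override")

validate_catalog <- function(catalog, require_unique = FALSE) {
  if (!is.data.frame(catalog)) stop("catalog must be a data frame", call. = FALSE)
  missing <- setdiff(setdiff(catalog_cols, "centroid_override"), names(catalog))
  if (length(missing)) {
    stop("catalog is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"centroid_override" %in% names(catalog)) {
    catalog$centroid_override <- NA_real_
  }
  catalog$centroid_override <- as.numeric(catalog$centroid_override)
  if (require_unique && anyDuplicated(catalog$object_id)) {
    stop("catalog object_id values must be unique", call. = FALSE)
  }
  if (any(catalog$bottom_radius <= 0) || any(catalog$height <= 0) ||
      any(catalog$top_radius < 0)) {
    stop("invalid object spec in catalog (radii/height out of range)",
         call. = FALSE)
  }
  if (!all(catalog$fill %in% c("solid", "hollow_shell"))) {
    stop("catalog fill must be 'solid' or 'hollow_shell'", call. = FALSE)
  }
  ok <- is.na(catalog$centroid_override) |
    (catalog$centroid_override > 0 & catalog$centroid_override < catalog$height)
  if (!all(ok)) {
    stop("centroid_override must lie strictly in (0, height)", call. = FALSE)
  }
  tibble::as_tibble(catalog[, catalog_cols])
}

#' Centroid height of a uniform solid frustum of revolution
#'
#' For bottom radius \eqn{R}, top radius \eqn{r} and height \eqn{h}, the
#' vertical centroid of the uniform solid is
#' \deqn{\bar z = \frac{h (R^2 + 2 R r + 3 r^2)}{4 (R^2 + R r + r^2)}.}
#' The cylinder (\eqn{r = R}) gives \eqn{h/2} and the cone (\eqn{r = 0})
#' gives \eqn{h/4}.
#'
#' @param bottom_radius,top_radius,height frustum dimensions (vectorised).
#' @return Centroid height above the base, strictly inside (0, height).
#' @export
solid_frustum_centroid <- function(bottom_radius, top_radius, height) {
  if (any(height <= 0) || any(bottom_radius <= 0)) {
    stop("invalid object spec: bottom_radius and height must be > 0",
         call. = FALSE)
  }
  R <- bottom_radius; r <- top_radius; h <- height
  h * (R^2 + 2 * R * r + 3 * r^2) / (4 * (R^2 + R * r + r^2))
}

#' Centroid height of a thin uniform frustum shell
#'
#' The lateral surface of a frustum has centroid height
#' \eqn{\bar z = h (R + 2 r) / (3 (R + r))}; a cylindrical shell gives
#' \eqn{h/2} and a conical shell \eqn{h/3}. With `include_base_cap = TRUE`
#' the bottom disk (area \eqn{\pi R^2}, centroid at 0) is combined by area
#' weighting.
#'
#' @inheritParams solid_frustum_centroid
#' @param include_base_cap include a closed bottom disk in the shell.
#' @return Centroid height above the base.
#' @export
shell_frustum_centroid <- function(bottom_radius, top_radius, height,
                                   include_base_cap = FALSE) {
  if (any(height <= 0) || any(bottom_radius <= 0)) {
    stop("invalid object spec: bottom_radius and height must be > 0",
         call. = FALSE)
  }
  R <- bottom_radius; r <- top_radius; h <- height
  if (any(R + r <= 0)) {
    stop("invalid object spec: R + r must be > 0 for a shell", call. = FALSE)
  }
  z_lat <- h * (R + 2 * r) / (3 * (R + r))
  if (!include_base_cap) return(z_lat)
  slant <- sqrt((R - r)^2 + h^2)
  a_lat <- pi * (R + r) * slant
  a_cap <- pi * R^2
  (a_lat * z_lat) / (a_lat + a_cap)
}

#' Vertical centroid height for catalog objects
#'
#' Dispatches on the `fill` column (solid vs hollow shell) and honours
#' `centroid_override` when present.
#'
#' @param catalog catalog tibble (see [object_spec()]).
#' @param include_base_cap passed to [shell_frustum_centroid()] for hollow
#'   objects.
#' @return Numeric vector of centroid heights, one per catalog row.
#' @export
centroid_height <- function(catalog, include_base_cap = FALSE) {
  catalog <- validate_catalog(catalog)
  z <- ifelse(
    catalog$fill == "solid",
    solid_frustum_centroid(catalog$bottom_radius, catalog$top_radius,
                           catalog$height),
    shell_frustum_centroid(catalog$bottom_radius, catalog$top_radius,
                           catalog$height, include_base_cap = include_base_cap)
  )
  ifelse(is.na(catalog$centroid_override), z, catalog$centroid_override)
}

#' Critical tipping angle of a stimulus object
#'
#' An object pivoting about its base rim (flush with the table edge, pivot
#' offset equal to the bottom radius \eqn{R}) tips off the support once its
#' centroid passes vertically above the pivot. That happens at the critical
#' angle \deqn{\theta_c = \arctan(R / \bar z)} (degrees), with \eqn{\bar z}
#' the vertical centroid height. Taller centroids mean smaller critical
#' angles: less stable objects.
#'
#' @inheritParams centroid_height
#' @return Critical angles in degrees, strictly inside (0, 90).
#' @export
critical_angle <- function(catalog, include_base_cap = FALSE) {
  catalog <- validate_catalog(catalog)
  z <- centroid_height(catalog, include_base_cap = include_base_cap)
  atan2(catalog$bottom_radius, z) * 180 / pi
}

#' Brute-force rotation oracle for the critical angle
#'
#' Independent numeric check on [critical_angle()]: the object is
#' discretised into mass elements (volume slabs for solids, lateral surface
#' bands plus optional base-cap rings for shells), every element is rotated
#' about the pivot (base rim point) in steps of `angular_step`, and the
#' smallest rotation at which the mass-weighted mean horizontal coordinate
#' crosses the pivot is bracketed and then refined by bisection on the same
#' rotated-element computation. No closed-form centroid or arctangent enters.
#'
#' @param spec one-row catalog tibble.
#' @param angular_step scan step in degrees; must be in (0, 5].
#' @param n_elements number of discretisation elements.
#' @param include_base_cap include the base disk for hollow shells.
#' @return Critical angle in degrees, with attributes `bracket_low` and
#'   `bracket_high` giving the scan bracket (width `angular_step`).
#' @export
numeric_critical_angle_oracle <- function(spec, angular_step = 0.5,
                                          n_elements = 4000L,
                                          include_base_cap = FALSE) {
  spec <- validate_catalog(spec)
  stopifnot(nrow(spec) == 1L)
  if (angular_step <= 0) stop("angular_step must be > 0", call. = FALSE)
  if (angular_step > 5) {
    stop("configuration error: angular_step too coarse to bracket (> 5 degrees)",
         call. = FALSE)
  }
  R <- spec$bottom_radius; r <- spec$top_radius; h <- spec$height
  # element centroids lie on the symmetry axis at x = -R relative to the pivot
  if (spec$fill == "solid") {
    z <- (seq_len(n_elements) - 0.5) * h / n_elements
    rad <- R + (r - R) * z / h
    w <- rad^2                       # slab volume ~ pi r(z)^2 dz
    x <- rep(-R, n_elements)
  } else {
    z <- (seq_len(n_elements) - 0.5) * h / n_elements
    rad <- R + (r - R) * z / h
    ds <- sqrt((R - r)^2 + h^2) / n_elements
    w <- rad * ds                    # band area ~ 2 pi r(z) ds
    x <- rep(-R, n_elements)
    if (include_base_cap) {
      rho <- (seq_len(n_elements) - 0.5) * R / n_elements
      w <- c(w, rho * (R / n_elements))  # ring area ~ 2 pi rho drho
      x <- c(x, rep(-R, n_elements))
      z <- c(z, rep(0, n_elements))
    }
  }
  if (!is.na(spec$centroid_override)) {
    # override collapses the mass distribution onto the stated centroid
    z <- spec$centroid_override; x <- -R; w <- 1
  }
  wsum <- sum(w)
  mean_x_rot <- function(theta_deg) {
    th <- theta_deg * pi / 180
    sum(w * (x * cos(th) + z * sin(th))) / wsum
  }
  # scan for the sign change, then bisect inside the bracket
  lo <- 0
  repeat {
    hi <- lo + angular_step
    if (hi > 180) stop("no crossing found below 180 degrees", call. = FALSE)
    if (mean_x_rot(hi) >= 0) break
    lo <- hi
  }
  bracket <- c(lo, hi)
  for (i in seq_len(60L)) {
    mid <- (lo + hi) / 2
    if (mean_x_rot(mid) >= 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-9) break
  }
  structure((lo + hi) / 2, bracket_low = bracket[1], bracket_high = bracket[2])
}

#' Ground-truth fall label for a tilted object
#'
#' Returns `"green"` (falls off the table onto the mat) when the tilt
#' exceeds the object's critical angle, `"red"` (falls back onto the table)
#' otherwise. A tilt exactly at the critical angle is labelled red: the
#' balanced case is resolved toward the table by convention.
#'
#' @param catalog catalog tibble; recycled against `tilt_deg`.
#' @param tilt_deg tilt angles in degrees, within \[0, 180\].
#' @inheritParams centroid_height
#' @return Character vector of `"green"` / `"red"` labels.
#' @export
fall_label <- function(catalog, tilt_deg, include_base_cap = FALSE) {
  if (any(tilt_deg < 0 | tilt_deg > 180)) {
    stop("tilt_deg must lie in [0, 180]", call. = FALSE)
  }
  theta_c <- critical_angle(catalog, include_base_cap = include_base_cap)
  ifelse(tilt_deg > theta_c, "green", "red")
}

#' Geometric feature table for a catalog
#'
#' The four geometric features used by the classifier models: base (width
#' of the bottom extent, \eqn{2R}), vertical centroid height, object height,
#' and the top/bottom (T/B) radius ratio.
#'
#' @inheritParams centroid_height
#' @return Tibble with columns `object_id`, `base`, `centroid`, `height`,
#'   `tb_ratio`.
#' @export
object_features <- function(catalog, include_base_cap = FALSE) {
  catalog <- validate_catalog(catalog)
  tibble::tibble(
    object_id = catalog$object_id,
    base = 2 * catalog$bottom_radius,
    centroid = centroid_height(catalog, include_base_cap = include_base_cap),
    height = catalog$height,
    tb_ratio = catalog$top_radius / catalog$bottom_radius
  )
}

#' Ground-truth table for a catalog
#'
#' @inheritParams centroid_height
#' @return Tibble with `object_id`, `critical_angle` (degrees),
#'   `centroid_height` and `pivot_offset` (= bottom radius).
#' @export
ground_truth <- function(catalog, include_base_cap = FALSE) {
  catalog <- validate_catalog(catalog)
  tibble::tibble(
    object_id = catalog$object_id,
    critical_angle = critical_angle(catalog, include_base_cap = include_base_cap),
    centroid_height = centroid_height(catalog, include_base_cap = include_base_cap),
    pivot_offset = catalog$bottom_radius
  )
}

#' Read / write object catalogs
#'
#' Catalogs are stored as CSV or YAML with columns/fields `object_id`,
#' `bottom_radius`, `top_radius`, `height`, `fill`, `centroid_override`.
#'
#' @param path file path; format chosen by extension (`.csv`, `.yaml`/`.yml`).
#' @return `read_catalog()` returns a validated catalog tibble.
#' @export
read_catalog <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    cat_raw <- readr::read_csv(path, show_col_types = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    lst <- yaml::read_yaml(path)
    cat_raw <- dplyr::bind_rows(lapply(lst, function(o) {
      o$centroid_override <- o$centroid_override %||% NA_real_
      tibble::as_tibble(o)
    }))
  } else {
    stop("unsupported catalog format: ", ext, call. = FALSE)
  }
  validate_catalog(cat_raw, require_unique = TRUE)
}

#' @rdname read_catalog
#' @param catalog catalog tibble to write.
#' @export
write_catalog <- function(catalog, path) {
  catalog <- validate_catalog(catalog)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    readr::write_csv(catalog, path)
  } else if (ext %in% c("yaml", "yml")) {
    lst <- lapply(seq_len(nrow(catalog)), function(i) {
      row <- as.list(catalog[i, ])
      if (is.na(row$centroid_override)) row$centroid_override <- NULL
      row
    })
    yaml::write_yaml(lst, path, precision = 15)
  } else {
    stop("unsupported catalog format: ", ext, call. = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
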