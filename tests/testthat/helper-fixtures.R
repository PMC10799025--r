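# Shared fixtures: tiny catalogs and designs built in code.

cylinder_spec <- function(h = 2, R = 1, id = "cyl") {
  object_spec(id, R, R, h, "solid")
}

cone_spec <- function(h = 4, R = 1, id = "cone") {
  object_spec(id, R, 0, h, "solid")
}

small_design <- function(objects, angle_min = 20, angle_max = 80,
                         angle_step = 5, repetitions = 2L,
                         sides = c("left", "right")) {
  experiment_design("test", angle_min, angle_max, angle_step, objects,
                    sides = sides, repetitions = repetitions)
}

# Binomial cell table drawn from a logistic observer, for direct fitting.
logistic_cells <- function(mid, scale, angles = seq(20, 80, 5), n = 100,
                           seed = 1) {
  withr::with_seed(seed, {
    p <- stats::plogis((angles - mid) / scale)
    tibble::tibble(angle_deg = angles,
                   n_green = stats::rbinom(length(angles), n, p),
                   n_total = n)
  })
}

# Independent midpoint-rule volume integration of z * A(z) for the solid
# frustum centroid (oracle for the closed form).
integrate_solid_centroid <- function(R, r, h, n = 1e6) {
  z <- (seq_len(n) - 0.5) * h / n
  rad <- R + (r - R) * z / h
  a <- rad^2
  sum(z * a) / sum(a)
}

# Independent triangulated-mesh surface oracle for shell centroids:
# area-weighted face centroids over an azimuthal x axial triangulation of
# the lateral surface, plus a fan triangulation of the base disk.
mesh_shell_centroid <- function(R, r, h, include_base_cap = FALSE,
                                n_phi = 400, n_z = 400) {
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)
  zs <- seq(0, h, length.out = n_z + 1)
  rad <- R + (r - R) * zs / h
  tri_area_z <- function(p1, p2, p3) {
    # p* are n x 3 matrices of triangle corners
    v1 <- p2 - p1; v2 <- p3 - p1
    cr <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
                v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
                v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
    a <- 0.5 * sqrt(rowSums(cr^2))
    c(sum(a), sum(a * (p1[, 3] + p2[, 3] + p3[, 3]) / 3))
  }
  tot <- c(0, 0)
  j <- seq_len(n_phi)
  for (i in seq_len(n_z)) {
    p00 <- cbind(rad[i] * cos(phi[j]), rad[i] * sin(phi[j]), zs[i])
    p01 <- cbind(rad[i] * cos(phi[j + 1]), rad[i] * sin(phi[j + 1]), zs[i])
    p10 <- cbind(rad[i + 1] * cos(phi[j]), rad[i + 1] * sin(phi[j]), zs[i + 1])
    p11 <- cbind(rad[i + 1] * cos(phi[j + 1]), rad[i + 1] * sin(phi[j + 1]),
                 zs[i + 1])
    tot <- tot + tri_area_z(p00, p01, p10) + tri_area_z(p01, p11, p10)
  }
  if (include_base_cap) {
    # fan triangulation of the base disk: all triangles lie at z = 0, so
    # only total area matters; use the polygonal (inscribed) area
    cap <- 0.5 * n_phi * R^2 * sin(2 * pi / n_phi)
    tot[1] <- tot[1] + cap
  }
  tot[2] / tot[1]
}
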