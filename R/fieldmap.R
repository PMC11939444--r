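#' Gridded field map over the sample plane
#'
#' Container for a 1 mm-pitch grid of simulated or measured field values in
#' the observation plane inside the Petri dish: a scalar power-flux grid
#' (W/m^2 per pixel) and/or complex three-component E (and optionally H)
#' fields. Statistics ([inhomogeneity_percent()], [polarization_ratios()],
#' [plane_wave_ratio()]) are evaluated over the Petri mask: the set of pixel
#' centers strictly inside the dish circle (default diameter 52 mm, centered
#' on the grid).
#'
#' @param power Numeric matrix of power-flux values (>= 0), or `NULL`.
#' @param e Optional list with complex matrices `x`, `y`, `z` (same dim).
#' @param h Optional list with complex matrices `x`, `y`, `z`.
#' @param pixel_size_m Pixel pitch in m (default 1e-3 = 1 mm).
#' @param petri_diameter_m Dish diameter in m (default 0.052).
#' @param petri_center Optional pixel-coordinate center `c(row, col)`;
#'   defaults to the grid center.
#' @param wave_impedance_ohm Wave impedance of the medium (default 377, air).
#' @return Object of class `rf_field_map`.
#' @export
field_map <- function(power = NULL, e = NULL, h = NULL,
                      pixel_size_m = 1e-3, petri_diameter_m = 0.052,
                      petri_center = NULL, wave_impedance_ohm = 377) {
  dims <- NULL
  if (!is.null(power)) {
    stopifnot(is.matrix(power), is.numeric(power))
    if (any(power < 0)) stop("`power` values must be >= 0", call. = FALSE)
    dims <- dim(power)
  }
  chk3 <- function(f, what) {
    stopifnot(is.list(f), all(c("x", "y", "z") %in% names(f)))
    for (cmp in c("x", "y", "z")) {
      m <- f[[cmp]]
      if (!is.matrix(m)) stop(what, "$", cmp, " must be a matrix",
                              call. = FALSE)
      if (!is.null(dims) && !identical(dim(m), as.integer(dims))) {
        stop("all grids in a field map must share dimensions", call. = FALSE)
      }
      dims <<- dim(m)
      f[[cmp]] <- matrix(as.complex(m), nrow = nrow(m))
    }
    f[c("x", "y", "z")]
  }
  if (!is.null(e)) e <- chk3(e, "e")
  if (!is.null(h)) h <- chk3(h, "h")
  if (is.null(dims)) stop("supply at least one of `power`, `e`", call. = FALSE)
  stopifnot(pixel_size_m > 0, petri_diameter_m > 0, wave_impedance_ohm > 0)
  if (is.null(petri_center)) petri_center <- (dims + 1) / 2
  structure(
    list(power = power, e = e, h = h,
         pixel_size_m = pixel_size_m,
         petri_diameter_m = petri_diameter_m,
         petri_center = petri_center,
         wave_impedance_ohm = wave_impedance_ohm,
         dims = dims),
    class = "rf_field_map"
  )
}

#' @export
print.rf_field_map <- function(x, ...) {
  cat(sprintf("Field map %d x %d px (%.3g mm pitch), Petri %.3g mm%s%s%s\n",
              x$dims[1], x$dims[2], x$pixel_size_m * 1e3,
              x$petri_diameter_m * 1e3,
              if (!is.null(x$power)) ", power" else "",
              if (!is.null(x$e)) ", E" else "",
              if (!is.null(x$h)) ", H" else ""))
  invisible(x)
}

#' Petri-dish pixel mask of a field map
#'
#' Pixel centers strictly inside the dish circle. Pixel (i, j) has center
#' coordinates `(i - center[1], j - center[2]) * pixel_size_m`.
#'
#' @param map An [field_map()] object.
#' @return Logical matrix, `TRUE` inside the dish.
#' @export
petri_mask <- function(map) {
  stopifnot(inherits(map, "rf_field_map"))
  r <- map$petri_diameter_m / 2
  ii <- (seq_len(map$dims[1]) - map$petri_center[1]) * map$pixel_size_m
  jj <- (seq_len(map$dims[2]) - map$petri_center[2]) * map$pixel_size_m
  outer(ii^2, jj^2, `+`) < r^2
}

#' Field inhomogeneity over the Petri dish, in percent
#'
#' The uniformity metric \eqn{100 \, \sigma(P) / \bar P} over the pixels
#' inside the Petri mask, with the population (not sample) standard
#' deviation: the masked grid is the whole population of pixels, not a draw
#' from one. Scale-invariant: multiplying the map by any k > 0 leaves it
#' unchanged.
#'
#' @param map A [field_map()] with a power grid.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Inhomogeneity in percent.
#' @export
inhomogeneity_percent <- function(map, sd_type = c("population", "sample")) {
  stopifnot(inherits(map, "rf_field_map"))
  sd_type <- match.arg(sd_type)
  if (is.null(map$power)) stop("field map has no power grid", call. = FALSE)
  p <- map$power[petri_mask(map)]
  if (length(p) < 2) stop("Petri mask covers fewer than 2 pixels",
                          call. = FALSE)
  m <- mean(p)
  if (m == 0) stop("all-zero power inside the Petri mask: inhomogeneity undefined",
                   call. = FALSE)
  s <- stats::sd(p)
  if (sd_type == "population") s <- s * sqrt((length(p) - 1) / length(p))
  100 * s / m
}

#' Polarization ratios of the E field over the Petri dish
#'
#' Ratios of mask-mean component magnitudes
#' \eqn{(\bar E_z / \bar E_x, \; \bar E_y / \bar E_x)}. Small ratios mean
#' the wave is predominantly linearly x-polarized, as expected in the far
#' field of the x-polarized patch antenna.
#'
#' @param map A [field_map()] with E components.
#' @return Named numeric vector `c(ez_ex = ..., ey_ex = ...)`.
#' @export
polarization_ratios <- function(map) {
  stopifnot(inherits(map, "rf_field_map"))
  if (is.null(map$e)) stop("field map has no E components", call. = FALSE)
  msk <- petri_mask(map)
  ex <- mean(Mod(map$e$x[msk]))
  if (ex == 0) stop("mask-mean |Ex| is zero: polarization ratios undefined",
                    call. = FALSE)
  c(ez_ex = mean(Mod(map$e$z[msk])) / ex,
    ey_ex = mean(Mod(map$e$y[msk])) / ex)
}

#' Plane-wave / Poynting power ratio over the Petri dish
#'
#' Far-field validity check: for a locally plane wave the time-averaged
#' Poynting magnitude \eqn{|\Re(\frac12 \vec E \times \vec H^*)|} equals the
#' E-only estimate \eqn{|E|^2 / 2\eta}. The statistic is the ratio of the
#' mask means of the two; it equals 1 exactly for an ideal plane wave with
#' \eqn{\vec H = \hat z \times \vec E / \eta}, and departs from 1 for
#' standing-wave or near-field structure. H is never assumed: maps without
#' H components raise an error.
#'
#' @param map A [field_map()] with both E and H components.
#' @return Dimensionless ratio (plane-wave estimate over Poynting).
#' @export
plane_wave_ratio <- function(map) {
  stopifnot(inherits(map, "rf_field_map"))
  if (is.null(map$e)) stop("field map has no E components", call. = FALSE)
  if (is.null(map$h)) {
    stop("cannot evaluate the plane-wave ratio without H components",
         call. = FALSE)
  }
  msk <- petri_mask(map)
  eta <- map$wave_impedance_ohm
  e2 <- Mod(map$e$x[msk])^2 + Mod(map$e$y[msk])^2 + Mod(map$e$z[msk])^2
  p_plane <- e2 / (2 * eta)
  # real part of (1/2) E x conj(H), then its vector magnitude
  sx <- Re(0.5 * (map$e$y[msk] * Conj(map$h$z[msk]) -
                  map$e$z[msk] * Conj(map$h$y[msk])))
  sy <- Re(0.5 * (map$e$z[msk] * Conj(map$h$x[msk]) -
                  map$e$x[msk] * Conj(map$h$z[msk])))
  sz <- Re(0.5 * (map$e$x[msk] * Conj(map$h$y[msk]) -
                  map$e$y[msk] * Conj(map$h$x[msk])))
  p_poynting <- sqrt(sx^2 + sy^2 + sz^2)
  if (mean(p_poynting) == 0) {
    stop("mask-mean Poynting power is zero: ratio undefined", call. = FALSE)
  }
  mean(p_plane) / mean(p_poynting)
}

#' Read / write field maps as CSV
#'
#' Two dialects are supported. A plain power grid is a headerless matrix CSV,
#' one value per pixel, row-major at the stated pitch. A component map is a
#' long-format CSV with columns `x_mm, y_mm, re_ex, im_ex, re_ey, im_ey,
#' re_ez, im_ez` and optionally the six `*_hx/hy/hz` counterparts plus
#' `power`.
#'
#' @param path File path.
#' @param ... Passed to [field_map()] (pitch, Petri geometry, impedance).
#' @return `read_power_map()` / `read_field_map()` return an
#'   [field_map()]; writers return `path` invisibly.
#' @export
read_power_map <- function(path, ...) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  field_map(power = m, ...)
}

#' @rdname read_power_map
#' @param map An `rf_field_map` with a power grid.
#' @export
write_power_map <- function(map, path) {
  stopifnot(inherits(map, "rf_field_map"), !is.null(map$power))
  utils::write.table(map$power, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname read_power_map
#' @export
read_field_map <- function(path, ...) {
  d <- utils::read.csv(path)
  need <- c("x_mm", "y_mm", "re_ex", "im_ex", "re_ey", "im_ey",
            "re_ez", "im_ez")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("field-map CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  xs <- sort(unique(d$x_mm)); ys <- sort(unique(d$y_mm))
  if (nrow(d) != length(xs) * length(ys)) {
    stop("field-map CSV is not a complete rectangular grid", call. = FALSE)
  }
  i <- match(d$x_mm, xs); j <- match(d$y_mm, ys)
  grid <- function(re, im) {
    m <- matrix(complex(real = 0, imaginary = 0), length(xs), length(ys))
    m[cbind(i, j)] <- complex(real = re, imaginary = im)
    m
  }
  e <- list(x = grid(d$re_ex, d$im_ex), y = grid(d$re_ey, d$im_ey),
            z = grid(d$re_ez, d$im_ez))
  h <- NULL
  if (all(c("re_hx", "im_hx", "re_hy", "im_hy", "re_hz", "im_hz") %in%
          names(d))) {
    h <- list(x = grid(d$re_hx, d$im_hx), y = grid(d$re_hy, d$im_hy),
              z = grid(d$re_hz, d$im_hz))
  }
  pw <- NULL
  if ("power" %in% names(d)) {
    pw <- matrix(0, length(xs), length(ys))
    pw[cbind(i, j)] <- d$power
  }
  field_map(power = pw, e = e, h = h, ...)
}

#' @rdname read_power_map
#' @export
write_field_map <- function(map, path) {
  stopifnot(inherits(map, "rf_field_map"), !is.null(map$e))
  idx <- expand.grid(i = seq_len(map$dims[1]), j = seq_len(map$dims[2]))
  at <- cbind(idx$i, idx$j)
  d <- data.frame(
    x_mm = idx$i, y_mm = idx$j,
    re_ex = Re(map$e$x[at]), im_ex = Im(map$e$x[at]),
    re_ey = Re(map$e$y[at]), im_ey = Im(map$e$y[at]),
    re_ez = Re(map$e$z[at]), im_ez = Im(map$e$z[at])
  )
  if (!is.null(map$h)) {
    d$re_hx <- Re(map$h$x[at]); d$im_hx <- Im(map$h$x[at])
    d$re_hy <- Re(map$h$y[at]); d$im_hy <- Im(map$h$y[at])
    d$re_hz <- Re(map$h$z[at]); d$im_hz <- Im(map$h$z[at])
  }
  if (!is.null(map$power)) d$power <- map$power[at]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
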