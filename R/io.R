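#' Spherical to interaural-polar coordinate conversion
#'
#' Converts azimuth/elevation (degrees; azimuth positive to the left) to
#' lateral/polar coordinates: `lat = asin(sin(azi) cos(ele))`, and the polar
#' angle from `atan2(sin(ele), cos(azi) cos(ele))` mapped into `[-90, 270)`
#' so it runs front-below -> up -> rear-below within a sagittal plane.
#'
#' @param azi,ele Azimuth and elevation in degrees.
#' @param lat,pol Lateral and polar angles in degrees.
#' @return A tibble with the converted coordinates in degrees.
#' @examples
#' sph_to_interaural(180, 0)  # rear: lat 0, pol 180
#' @export
sph_to_interaural <- function(azi, ele) {
  a <- azi * pi / 180
  e <- ele * pi / 180
  lat <- asin(sin(a) * cos(e))
  pol <- atan2(sin(e), cos(a) * cos(e)) * 180 / pi
  pol <- ifelse(pol < -90, pol + 360, pol)
  tibble::tibble(lat = lat * 180 / pi, pol = pol)
}

#' @rdname sph_to_interaural
#' @export
interaural_to_sph <- function(lat, pol) {
  l <- lat * pi / 180
  p <- pol * pi / 180
  x <- cos(l) * cos(p)  # front
  y <- sin(l)           # left
  z <- cos(l) * sin(p)  # up
  tibble::tibble(azi = atan2(y, x) * 180 / pi,
                 ele = asin(pmin(pmax(z, -1), 1)) * 180 / pi)
}

#' Remove direction-independent spectral characteristics
#'
#' Converts HRTF log-magnitude spectra into DTFs: per ear, the mean
#' log-magnitude across all measured directions is subtracted from each
#' direction, leaving only the direction-dependent filtering.
#'
#' @param mag_db Matrix of log-magnitude spectra (directions x frequencies)
#'   for one ear.
#' @return Matrix of the same shape whose column means are zero.
#' @export
dtf_from_hrtf <- function(mag_db) {
  if (!is.matrix(mag_db) || nrow(mag_db) < 2)
    stop("need a directions-by-frequency matrix with >= 2 directions",
         call. = FALSE)
  sweep(mag_db, 2, colMeans(mag_db))
}

#' Read and write localization response tables
#'
#' Plain CSV with header, angles in degrees, columns `subject_id`,
#' `target_lat`, `target_pol`, `response_lat`, `response_pol`.
#'
#' @param path File path.
#' @param responses Response tibble.
#' @return `read_responses_csv()` returns a `response_set` tibble.
#' @export
read_responses_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = readr::col_character(),
                           .default = readr::col_double()))
  need <- c("subject_id", "target_lat", "target_pol",
            "response_lat", "response_pol")
  if (!all(need %in% names(out)))
    stop("response CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  class(out) <- c("response_set", class(out))
  out
}

#' @rdname read_responses_csv
#' @export
write_responses_csv <- function(responses, path) {
  readr::write_csv(responses, path)
  invisible(path)
}

#' Serialize a weighting scheme to a two-column table
#'
#' @param scheme A [weighting_scheme()].
#' @param path File path.
#' @param grid The [erb_bands()] grid to attach when reading back.
#' @param name,level Scheme metadata for the read-back object.
#' @return `read_scheme_csv()` returns a [weighting_scheme()].
#' @export
write_scheme_csv <- function(scheme, path) {
  readr::write_csv(scheme[, c("cf_hz", "weight")], path)
  invisible(path)
}

#' @rdname write_scheme_csv
#' @export
read_scheme_csv <- function(path, grid, name = "custom", level = "group") {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("cf_hz", "weight") %in% names(tab)))
    stop("scheme CSV must have columns cf_hz, weight", call. = FALSE)
  if (max(abs(tab$cf_hz - grid$cf_hz[-1])) > 1e-6)
    stop("scheme CSV band centers do not match the grid", call. = FALSE)
  weighting_scheme(tab$weight, grid, name, level)
}

#' Read and write DTF sets as plain long-format spectral tables
#'
#' The interchange format for directional transfer functions is a plain CSV
#' with one row per (plane, direction, ear, frequency): columns `lateral`,
#' `polar`, `ear`, `freq_hz`, `gain_db`.
#'
#' @param dtf A `dtf` element as returned by [make_dtf_set()].
#' @param path File path.
#' @return `read_dtf_table()` returns a `dtf` list (`freq_hz`, `planes`).
#' @export
write_dtf_table <- function(dtf, path) {
  rows <- purrr::map_dfr(dtf$planes, function(p) {
    purrr::map_dfr(c("left", "right"), function(ear) {
      m <- p[[paste0(ear, "_db")]]
      tibble::tibble(lateral = p$lateral,
                     polar = rep(p$theta, each = length(dtf$freq_hz)),
                     ear = ear,
                     freq_hz = rep(dtf$freq_hz, length(p$theta)),
                     gain_db = as.numeric(t(m)))
    })
  })
  readr::write_csv(rows, path)
  invisible(path)
}

#' @rdname write_dtf_table
#' @export
read_dtf_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  freq <- sort(unique(tab$freq_hz))
  planes <- lapply(split(tab, tab$lateral), function(pp) {
    theta <- sort(unique(pp$polar))
    grab <- function(ear) {
      sub <- pp[pp$ear == ear, ]
      sub <- sub[order(sub$polar, sub$freq_hz), ]
      matrix(sub$gain_db, nrow = length(theta), byrow = TRUE)
    }
    list(lateral = pp$lateral[1], theta = theta,
         left_db = grab("left"), right_db = grab("right"))
  })
  list(freq_hz = freq, planes = planes)
}

#' Run configuration with a stable content hash
#'
#' Bundles the tunable constants of an analysis run (band grid limits,
#' scheme parameters, binaural scale, PMV floor, fit bounds, seeds, plane
#' definitions) and attaches a hash that changes iff any field changes, for
#' logging and artifact provenance.
#'
#' @param ... Named configuration fields overriding the defaults.
#' @return Named list of class `run_config` with attribute `hash`.
#' @export
run_config <- function(...) {
  cfg <- utils::modifyList(list(
    f_low = 700, f_high = 18000, erb_step = 1,
    nr_center_hz = 8000, dt_center_hz = 6000, bump_width_oct = 1,
    bump_floor = 0.05, lp_decay = 0.5,
    phi_scale = 13, bin_deg = 5, pmv_floor = 1e-9,
    bounds = unclass(fit_bounds()), boundary_tol = 0.01,
    lateral_range = c(-10, 10),
    lateral_planes = c(0, -20, 20, -40, 40, -60, 60, -80, 80),
    seed = 1), list(...))
  structure(cfg, class = "run_config", hash = rlang::hash(cfg))
}
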