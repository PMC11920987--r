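#' Construct a spectral weighting scheme
#'
#' A weighting scheme assigns one non-negative weight to each gradient band
#' (bands `2..Nb` of an [erb_bands()] grid, i.e. the bands on which positive
#' spectral gradients are defined). Weights are normalized to unit sum so that
#' the distance metric stays a weighted average of absolute gradient
#' differences whatever the scheme — this keeps fitted model parameters
#' comparable across schemes.
#'
#' @param weights Non-negative numeric vector, length `nrow(grid) - 1`.
#' @param grid An [erb_bands()] grid.
#' @param name Scheme label, e.g. `"Flat"`, `"NR"`, `"DT"`, `"SV"`, `"LP"`.
#' @param level `"group"` or `"subject"`.
#' @param lateral_plane Lateral angle (deg) of the sagittal plane the scheme
#'   belongs to, if plane-specific (SV); `NA` otherwise.
#' @param subject_id Subject identifier for subject-level schemes.
#' @return A tibble of class `weighting_scheme` with columns `band`, `cf_hz`
#'   and `weight` (summing to 1).
#' @export
weighting_scheme <- function(weights, grid, name, level = "group",
                             lateral_plane = NA_real_, subject_id = NA_character_) {
  nb <- nrow(grid)
  if (length(weights) != nb - 1)
    stop("need one weight per gradient band (", nb - 1, ")", call. = FALSE)
  if (any(weights < 0) || any(!is.finite(weights)))
    stop("weights must be finite and non-negative", call. = FALSE)
  s <- sum(weights)
  if (s <= 0) stop("weights must not be all zero", call. = FALSE)
  out <- tibble::tibble(band = grid$band[-1], cf_hz = grid$cf_hz[-1],
                        weight = weights / s)
  structure(out,
            class = c("weighting_scheme", class(tibble::tibble())),
            scheme_name = name, level = level,
            lateral_plane = lateral_plane, subject_id = subject_id)
}

#' @export
print.weighting_scheme <- function(x, ...) {
  cat(sprintf("<weighting_scheme> %s (%s level)\n",
              attr(x, "scheme_name"), attr(x, "level")))
  NextMethod()
}

#' Flat weighting scheme
#'
#' Equal weight in every gradient band: the weighting used by the original
#' template-matching localization model.
#'
#' @inheritParams weighting_scheme
#' @return A [weighting_scheme()].
#' @export
scheme_flat <- function(grid) {
  weighting_scheme(rep(1, nrow(grid) - 1), grid, "Flat")
}

#' Gaussian-bump weighting schemes (NR and DT)
#'
#' A log-frequency Gaussian emphasis on top of a constant floor:
#' `w ∝ floor + (1 - floor) * exp(-log2(f / center)^2 / (2 * width^2))`.
#' `scheme_nr()` centers the bump at 8 kHz, the region where the main pinna
#' notch migrates with elevation; `scheme_dt()` centers it at 6 kHz, the
#' region emphasized by elevation discrimination experiments.
#'
#' @inheritParams weighting_scheme
#' @param center_hz Bump center frequency in Hz (within the grid span).
#' @param width_oct Gaussian SD in octaves (default 1).
#' @param floor Constant baseline as a fraction of the peak, in `[0, 1)`.
#' @return A [weighting_scheme()].
#' @export
scheme_bump <- function(grid, center_hz, width_oct = 1, floor = 0.05,
                        name = "bump") {
  if (width_oct <= 0) stop("`width_oct` must be positive", call. = FALSE)
  if (floor < 0 || floor >= 1) stop("`floor` must be in [0, 1)", call. = FALSE)
  f <- grid$cf_hz[-1]
  if (center_hz < min(grid$cf_hz) || center_hz > max(grid$cf_hz))
    stop("`center_hz` outside the band grid span", call. = FALSE)
  z <- log2(f / center_hz) / width_oct
  w <- floor + (1 - floor) * exp(-0.5 * z^2)
  weighting_scheme(w, grid, name)
}

#' @rdname scheme_bump
#' @export
scheme_nr <- function(grid, width_oct = 1, floor = 0.05) {
  scheme_bump(grid, 8000, width_oct, floor, name = "NR")
}

#' @rdname scheme_bump
#' @export
scheme_dt <- function(grid, width_oct = 1, floor = 0.05) {
  scheme_bump(grid, 6000, width_oct, floor, name = "DT")
}

#' Low-pass weighting scheme
#'
#' Exponentially decaying weights, `w ∝ decay^log2(f / f0)`, i.e. the weight
#' is multiplied by `decay` per octave above the lowest band. Models a
#' listener upweighting the low-frequency region where natural sounds carry
#' most energy.
#'
#' @inheritParams weighting_scheme
#' @param decay Per-octave multiplicative factor in `(0, 1)`.
#' @return A [weighting_scheme()] with strictly decreasing weights.
#' @export
scheme_lp <- function(grid, decay = 0.5) {
  if (decay <= 0 || decay >= 1)
    stop("`decay` must be in (0, 1) for a decreasing scheme", call. = FALSE)
  f <- grid$cf_hz[-1]
  w <- decay^(log2(f / grid$cf_hz[1]))
  weighting_scheme(w, grid, "LP")
}

#' Acoustic spatial variance of a listener's templates
#'
#' For one sagittal plane, the spatial variance `nu[b]` of a listener's
#' gradient templates is the variance of the template PSG across the polar
#' dimension, computed per ear, combined across ears with the binaural weight
#' `alpha` for that plane, and symmetrized with the mirrored plane:
#' `nu[phi_k] = 0.5 * (vL[phi_k] a + vR[phi_k] (1-a) + vL[-phi_k] (1-a) + vR[-phi_k] a)`,
#' which makes `nu[phi_k] == nu[-phi_k]` exactly. Variances are population
#' variances (divide by N): the polar grid is a census of template
#' directions, not a sample.
#'
#' @param templates A [template_set()].
#' @param lateral_plane Lateral angle (deg) of the plane; its mirror plane
#'   must also be present in `templates` (the median plane is its own mirror).
#' @param phi_scale Binaural weighting scale in degrees (see
#'   [binaural_weight()]).
#' @return A tibble with columns `band`, `cf_hz`, `nu`, carrying the
#'   per-ear/per-plane variance components in attribute `components`.
#' @export
spatial_variance <- function(templates, lateral_plane, phi_scale = 13) {
  # canonicalize to the non-negative plane: alpha(-phi) = 1 - alpha(phi)
  # makes the formula mirror-symmetric, so +/-phi give the same terms and
  # computing them in one fixed order keeps the symmetry bit-exact
  lat <- abs(lateral_plane)
  pk <- template_plane(templates, lat)
  pm <- template_plane(templates, -lat)
  pop_var <- function(m) apply(m, 2, function(x) mean((x - mean(x))^2))
  v <- list(l_k = pop_var(pk$left),  r_k = pop_var(pk$right),
            l_m = pop_var(pm$left),  r_m = pop_var(pm$right))
  a <- binaural_weight(lat, phi_scale)
  nu <- 0.5 * (v$l_k * a + v$r_k * (1 - a) + v$l_m * (1 - a) + v$r_m * a)
  grid <- templates$grid
  structure(tibble::tibble(band = grid$band[-1], cf_hz = grid$cf_hz[-1], nu = nu),
            components = v, lateral_plane = lateral_plane)
}

#' Spatial-variance (SV) weighting scheme
#'
#' Normalizes per-band spatial variances into a subject-level weighting
#' scheme: bands in which the listener's own templates vary more across polar
#' angle — and therefore carry more spatial information — get more weight.
#'
#' @param nu A tibble from [spatial_variance()].
#' @param grid The [erb_bands()] grid the variances were computed on.
#' @inheritParams weighting_scheme
#' @return A [weighting_scheme()] with `name = "SV"`.
#' @export
scheme_sv <- function(nu, grid, subject_id = NA_character_) {
  if (sum(nu$nu) <= 0)
    stop("all-zero spatial variance: templates carry no spatial information",
         call. = FALSE)
  weighting_scheme(nu$nu, grid, "SV", level = "subject",
                   lateral_plane = attr(nu, "lateral_plane"),
                   subject_id = subject_id)
}

#' Group-level scheme from subject-level schemes
#'
#' Arithmetic mean of subject-level weights per band, renormalized; all
#' schemes must share the same band grid and lateral plane.
#'
#' @param schemes List of [weighting_scheme()] objects.
#' @return A group-level [weighting_scheme()].
#' @export
scheme_group_average <- function(schemes) {
  if (length(schemes) == 0) stop("empty scheme list", call. = FALSE)
  cf <- schemes[[1]]$cf_hz
  for (s in schemes)
    if (!isTRUE(all.equal(s$cf_hz, cf)))
      stop("schemes do not share a band grid", call. = FALSE)
  w <- rowMeans(vapply(schemes, function(s) s$weight, numeric(length(cf))))
  out <- tibble::tibble(band = schemes[[1]]$band, cf_hz = cf,
                        weight = w / sum(w))
  structure(out,
            class = class(schemes[[1]]),
            scheme_name = attr(schemes[[1]], "scheme_name"),
            level = "group",
            lateral_plane = attr(schemes[[1]], "lateral_plane"),
            subject_id = NA_character_)
}

#' The five standard weighting schemes for a listener pool
#'
#' Convenience constructor for the model variants compared in the package:
#' Flat, NR (notch region, 8 kHz bump), DT (discrimination task, 6 kHz bump),
#' SV (group-level spatial variance computed from the supplied listeners'
#' median-plane templates) and LP (low-pass decay).
#'
#' @param listeners List of [template_set()] objects (used for SV).
#' @param grid An [erb_bands()] grid.
#' @param lateral_plane Plane for the SV weights (default median plane).
#' @return Named list of five [weighting_scheme()] objects.
#' @export
standard_schemes <- function(listeners, grid, lateral_plane = 0) {
  svs <- lapply(listeners, function(tpl) {
    scheme_sv(spatial_variance(tpl, lateral_plane), grid,
              subject_id = tpl$subject_id)
  })
  list(Flat = scheme_flat(grid),
       NR   = scheme_nr(grid),
       DT   = scheme_dt(grid),
       SV   = scheme_group_average(svs),
       LP   = scheme_lp(grid))
}
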