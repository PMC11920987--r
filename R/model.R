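#' Template set of a listener
#'
#' Container for a listener's internal templates: per sagittal plane, the
#' positive-spectral-gradient (PSG) profiles of the listener's DTFs, one row
#' per polar angle and one column per gradient band, for each ear. The polar
#' angle convention is `theta` in `[-90, 270)` degrees, running front-below
#' -> up -> rear-below; the lateral convention is positive = left.
#'
#' @param subject_id Listener identifier.
#' @param grid The [erb_bands()] grid shared by all templates.
#' @param planes Named list (names = lateral angle in degrees); each element
#'   a list with `lateral` (deg), `theta` (strictly increasing polar grid in
#'   `[-90, 270)`), and matrices `left`, `right` of dimension
#'   `length(theta) x (nrow(grid) - 1)` with non-negative PSG values.
#' @return An object of class `template_set`.
#' @export
template_set <- function(subject_id, grid, planes) {
  nbg <- nrow(grid) - 1
  for (p in planes) {
    stopifnot(is.numeric(p$theta), !is.unsorted(p$theta, strictly = TRUE),
              all(p$theta >= -90), all(p$theta < 270),
              is.matrix(p$left), is.matrix(p$right),
              all(dim(p$left) == c(length(p$theta), nbg)),
              all(dim(p$right) == c(length(p$theta), nbg)),
              all(p$left >= 0), all(p$right >= 0))
  }
  structure(list(subject_id = subject_id, grid = grid, planes = planes),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> subject %s: %d band(s), planes at %s deg\n",
              x$subject_id, nrow(x$grid) - 1,
              paste(vapply(x$planes, `[[`, numeric(1), "lateral"),
                    collapse = ", ")))
  invisible(x)
}

template_plane <- function(templates, lateral_plane) {
  lats <- vapply(templates$planes, `[[`, numeric(1), "lateral")
  i <- which(abs(lats - lateral_plane) < 1e-9)
  if (length(i) != 1)
    stop("no template plane at lateral angle ", lateral_plane, " deg",
         call. = FALSE)
  templates$planes[[i]]
}

#' Model parameters
#'
#' The three free parameters of the localization model: `gamma`, the degree
#' of selectivity (slope of the distance-to-similarity sigmoid); `s`, the
#' sensitivity (horizontal shift of the sigmoid, in dB of weighted gradient
#' distance); and `epsilon`, the sensorimotor scatter (SD in degrees of the
#' Gaussian response smearing).
#'
#' @param gamma Positive selectivity.
#' @param s Sensitivity (dimensionless, same units as the distance metric).
#' @param epsilon Positive scatter in degrees.
#' @return A named list of class `model_params`.
#' @export
model_params <- function(gamma, s, epsilon) {
  stopifnot(is.numeric(gamma), gamma > 0, is.numeric(s),
            is.numeric(epsilon), epsilon > 0)
  structure(list(gamma = gamma, s = s, epsilon = epsilon),
            class = "model_params")
}

#' Weighted gradient distance profile
#'
#' Distance between a target PSG profile and each template of one ear along
#' one sagittal plane: `d[theta] = sum_b |template[theta, b] - target[b]| * w[b]`.
#' With unit-sum weights this is a weighted mean absolute gradient
#' difference, in dB.
#'
#' @param templates A [template_set()].
#' @param target_psg Numeric target PSG profile (length = gradient bands).
#' @param scheme A [weighting_scheme()] on the same grid.
#' @param ear `"left"` or `"right"`.
#' @param lateral_plane Plane to compare against.
#' @return Numeric vector `d` over the plane's polar grid, all entries >= 0.
#' @export
distance_profile <- function(templates, target_psg, scheme,
                             ear = c("left", "right"), lateral_plane = 0) {
  ear <- match.arg(ear)
  p <- template_plane(templates, lateral_plane)
  tpl <- p[[ear]]
  if (length(target_psg) != ncol(tpl))
    stop("target profile has ", length(target_psg), " bands, templates have ",
         ncol(tpl), call. = FALSE)
  if (nrow(scheme) != ncol(tpl))
    stop("weighting scheme does not match the template band grid",
         call. = FALSE)
  as.numeric(abs(sweep(tpl, 2, target_psg)) %*% scheme$weight)
}

#' Distance-to-similarity sigmoid
#'
#' Maps a distance profile to a similarity index in (0, 1):
#' `sigma = 1 - 1 / (1 + exp(-gamma * (d - s)))`, strictly decreasing in the
#' distance, with midpoint at `d = s` and slope set by `gamma`.
#'
#' @param d Numeric distance values (>= 0).
#' @param gamma Selectivity (> 0).
#' @param s Sensitivity.
#' @return Similarity values in (0, 1).
#' @export
similarity <- function(d, gamma, s) {
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  stats::plogis(-gamma * (d - s))
}

#' Binaural weighting of the ipsilateral ear
#'
#' Logistic weight of the left ear as a function of lateral angle (positive
#' = left): `alpha(phi) = 1 / (1 + exp(-phi / phi_scale))`. At the median
#' plane the ears are weighted equally; towards the side the ipsilateral ear
#' dominates. The default scale of 13 degrees reproduces the binaural
#' weighting used in sagittal-plane localization modelling (after
#' Macpherson & Sabin).
#'
#' @param lateral Lateral angle in degrees (positive = left).
#' @param phi_scale Logistic scale in degrees.
#' @return Left-ear weight in (0, 1); exactly 0.5 at `lateral = 0`.
#' @export
binaural_weight <- function(lateral, phi_scale = 13) {
  stats::plogis(lateral / phi_scale)
}

#' Combine monaural similarity profiles binaurally
#'
#' Weighted sum of the two ears' similarity profiles, with the weight of the
#' left ear given by [binaural_weight()] so that the ear on the source side
#' dominates away from the median plane.
#'
#' @param sigma_left,sigma_right Similarity profiles over the same polar grid.
#' @param lateral Lateral angle of the plane in degrees (positive = left).
#' @param phi_scale Binaural weighting scale in degrees.
#' @return Combined similarity profile.
#' @export
binaural_combine <- function(sigma_left, sigma_right, lateral, phi_scale = 13) {
  stopifnot(length(sigma_left) == length(sigma_right))
  a <- binaural_weight(lateral, phi_scale)
  a * sigma_left + (1 - a) * sigma_right
}

# wrapped-Gaussian circulant kernel over a periodic polar grid; columns sum to 1
smear_kernel <- function(theta, epsilon, period = 360, n_wrap = 2) {
  d <- outer(theta, theta, "-")
  k <- 0
  for (m in -n_wrap:n_wrap)
    k <- k + exp(-(d + m * period)^2 / (2 * epsilon^2))
  sweep(k, 2, colSums(k), "/")
}

#' Sensorimotor scatter as circular Gaussian smearing
#'
#' Convolves a response profile with a wrapped Gaussian kernel of SD
#' `epsilon` along the circular polar dimension (period 360 deg), modelling
#' the scatter between the perceived direction and the pointing response.
#' The kernel is normalized so total mass is preserved.
#'
#' @param profile Non-negative profile over `theta`.
#' @param epsilon Scatter SD in degrees (> 0).
#' @param theta Polar grid in degrees (regular spacing assumed).
#' @return Smeared profile, same length and same sum as `profile`.
#' @export
sensorimotor_smear <- function(profile, epsilon, theta) {
  if (epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
  stopifnot(length(profile) == length(theta))
  as.numeric(smear_kernel(theta, epsilon) %*% profile)
}

#' Normalize a response profile to a probability mass vector
#'
#' @param profile Non-negative profile over the polar grid, not all zero.
#' @param theta Polar bin centers in degrees.
#' @return A tibble of class `pmv` with columns `polar_deg` and `prob`
#'   (summing to 1).
#' @export
to_pmv <- function(profile, theta) {
  stopifnot(length(profile) == length(theta))
  if (any(profile < 0)) stop("profile must be non-negative", call. = FALSE)
  s <- sum(profile)
  if (s <= 0) stop("all-zero profile cannot be normalized", call. = FALSE)
  out <- tibble::tibble(polar_deg = theta, prob = profile / s)
  class(out) <- c("pmv", class(out))
  out
}

# target PSG per ear at an arbitrary polar angle: linear interpolation of the
# plane's template PSG along theta (exact at grid angles)
target_psg_profile <- function(plane, target_pol, ear) {
  tpl <- plane[[ear]]
  th <- plane$theta
  if (target_pol < min(th) || target_pol > max(th))
    stop("target polar angle ", target_pol, " outside template coverage",
         call. = FALSE)
  i <- findInterval(target_pol, th, rightmost.closed = TRUE)
  if (th[i] == target_pol) return(tpl[i, ])
  w <- (target_pol - th[i]) / (th[i + 1] - th[i])
  (1 - w) * tpl[i, ] + w * tpl[i + 1, ]
}

#' Predict the response probability mass vector for a target
#'
#' Full forward pass of the localization model for one target direction:
#' target PSG extraction from the listener's own DTF templates, weighted
#' gradient distance per ear, similarity sigmoid, binaural combination,
#' sensorimotor smearing, and normalization to a PMV over the plane's polar
#' grid.
#'
#' @param templates A [template_set()].
#' @param target_lat,target_pol Target direction in interaural-polar
#'   coordinates (deg); the plane at `target_lat` must exist in `templates`.
#' @param params A [model_params()].
#' @param scheme A [weighting_scheme()].
#' @param phi_scale Binaural weighting scale in degrees.
#' @return A `pmv` tibble (see [to_pmv()]).
#' @examples
#' tpl <- make_dtf_set(synthetic_listener_spec(rng_seed = 1))$templates
#' pmv <- predict_pmv(tpl, 0, 30, model_params(6, 0.7, 12.79), scheme_flat(tpl$grid))
#' pmv$polar_deg[which.max(pmv$prob)]
#' @export
predict_pmv <- function(templates, target_lat, target_pol, params, scheme,
                        phi_scale = 13) {
  m <- pmv_matrix(templates, tibble::tibble(lat = target_lat, pol = target_pol),
                  params, scheme, lateral_plane = target_lat,
                  phi_scale = phi_scale)
  to_pmv(m$pmv[, 1], m$theta)
}

# PMVs for many targets of one plane at once. targets: tibble(lat, pol).
# Returns list(theta, pmv = matrix bins x targets).
pmv_matrix <- function(templates, targets, params, scheme, lateral_plane,
                       phi_scale = 13) {
  p <- template_plane(templates, lateral_plane)
  dl <- vapply(targets$pol, function(tp)
    distance_profile(templates, target_psg_profile(p, tp, "left"),
                     scheme, "left", lateral_plane),
    numeric(length(p$theta)))
  dr <- vapply(targets$pol, function(tp)
    distance_profile(templates, target_psg_profile(p, tp, "right"),
                     scheme, "right", lateral_plane),
    numeric(length(p$theta)))
  pmv_from_distances(dl, dr, p$theta, lateral_plane, params, phi_scale)
}

# core forward pass from precomputed distance matrices (bins x targets)
pmv_from_distances <- function(dl, dr, theta, lateral, params, phi_scale = 13) {
  sl <- similarity(dl, params$gamma, params$s)
  sr <- similarity(dr, params$gamma, params$s)
  comb <- binaural_weight(lateral, phi_scale) * sl +
    (1 - binaural_weight(lateral, phi_scale)) * sr
  sm <- smear_kernel(theta, params$epsilon) %*% comb
  cs <- colSums(sm)
  zero <- cs <= 0  # similarity underflowed everywhere: uniform fallback
  if (any(zero)) {
    sm[, zero] <- 1
    cs[zero] <- nrow(sm)
  }
  list(theta = theta, pmv = sweep(sm, 2, cs, "/"))
}
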