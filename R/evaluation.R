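#' Signed circular polar error
#'
#' Angular disparity between target and response polar angles, wrapped into
#' `[-180, 180)` on the circular polar dimension (so errors across the
#' -90/270 seam are measured the short way around).
#'
#' @param target_pol,response_pol Polar angles in degrees (vectorized).
#' @return Signed error in degrees, in `[-180, 180)`.
#' @examples
#' polar_error(-80, 260)  # -20: the response is 20 deg away across the seam
#' @export
polar_error <- function(target_pol, response_pol) {
  (response_pol - target_pol + 180) %% 360 - 180
}

#' Quadrant error rate and local polar error
#'
#' The two standard sagittal-plane localization metrics. QE is the
#' percentage of non-local responses, i.e. with absolute polar error larger
#' than 90 deg; PE is the root-mean-square polar error over the local
#' responses (absolute error smaller than or equal to 90 deg, so an exact
#' 90-deg error counts as local). Errors are computed on the raw response
#' angles.
#'
#' @param responses Tibble with columns `target_pol` and `response_pol`
#'   (e.g. a [simulate_responses()] table).
#' @return One-row tibble (`qe` in percent, `pe` in degrees, `n_local`,
#'   `n_total`); `pe` is `NA` when no local responses exist.
#' @examples
#' qe_pe(tibble::tibble(target_pol = 0, response_pol = c(10, -10, 30, 200)))
#' @export
qe_pe <- function(responses) {
  if (nrow(responses) == 0) stop("empty response set", call. = FALSE)
  err <- abs(polar_error(responses$target_pol, responses$response_pol))
  local <- err <= 90
  tibble::tibble(
    qe = 100 * mean(!local),
    pe = if (any(local)) sqrt(mean(err[local]^2)) else NA_real_,
    n_local = sum(local),
    n_total = length(err))
}

#' Per-subject localization metrics
#'
#' @param responses Response tibble with a `subject_id` column.
#' @return Tibble with one [qe_pe()] row per subject.
#' @export
localization_metrics <- function(responses) {
  dplyr::group_modify(dplyr::group_by(responses, .data$subject_id),
                      ~ qe_pe(.x)) |> dplyr::ungroup()
}
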