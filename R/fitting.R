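#' Parameter bounds for model fitting
#'
#' Plausible ranges for the three model parameters, used both to constrain
#' the likelihood maximization and to flag non-convergence at a boundary.
#'
#' @param gamma,s,epsilon Length-2 numeric `(lower, upper)` vectors.
#' @return A list of class `fit_bounds`.
#' @export
fit_bounds <- function(gamma = c(0.1, 100), s = c(-20, 20),
                       epsilon = c(3, 50)) {
  b <- list(gamma = gamma, s = s, epsilon = epsilon)
  for (nm in names(b))
    if (length(b[[nm]]) != 2 || b[[nm]][1] >= b[[nm]][2])
      stop("bound `", nm, "` must be (lower, upper) with lower < upper",
           call. = FALSE)
  structure(b, class = "fit_bounds")
}

# assign responses to nearest polar bin (circular); ties go to the lower bin
assign_bins <- function(response_pol, theta) {
  spacing <- theta[2] - theta[1]
  off <- (response_pol - theta[1]) %% 360
  idx <- ceiling(off / spacing - 0.5) %% length(theta) + 1
  as.integer(idx)
}

# precomputed likelihood machinery shared by log_likelihood and fit_subject;
# returns function(gamma, s, epsilon) -> log-likelihood
make_loglik <- function(responses, templates, scheme,
                        lateral_range = c(-10, 10), phi_scale = 13,
                        floor = 1e-9) {
  r <- responses[responses$target_lat > lateral_range[1] &
                   responses$target_lat < lateral_range[2], ]
  if (nrow(r) == 0)
    stop("no responses within the lateral range (",
         lateral_range[1], ", ", lateral_range[2], ")", call. = FALSE)
  plane_ctx <- lapply(split(r, r$target_lat), function(rr) {
    lat <- rr$target_lat[1]
    p <- template_plane(templates, lat)
    pols <- sort(unique(rr$target_pol))
    dl <- vapply(pols, function(tp)
      distance_profile(templates, target_psg_profile(p, tp, "left"),
                       scheme, "left", lat), numeric(length(p$theta)))
    dr <- vapply(pols, function(tp)
      distance_profile(templates, target_psg_profile(p, tp, "right"),
                       scheme, "right", lat), numeric(length(p$theta)))
    bins <- assign_bins(rr$response_pol, p$theta)
    counts <- matrix(0, length(p$theta), length(pols))
    ti <- match(rr$target_pol, pols)
    for (k in seq_along(bins)) counts[bins[k], ti[k]] <-
        counts[bins[k], ti[k]] + 1
    # squared wrapped offsets, reused to rebuild the smear kernel cheaply
    dth <- outer(p$theta, p$theta, "-")
    sq <- lapply(-2:2, function(m) (dth + 360 * m)^2)
    list(lat = lat, theta = p$theta, dl = dl, dr = dr, counts = counts,
         sq = sq, a = binaural_weight(lat, phi_scale))
  })
  n_trials <- nrow(r)
  f <- function(gamma, s, epsilon) {
    ll <- 0
    inv2e2 <- 1 / (2 * epsilon^2)
    for (cx in plane_ctx) {
      comb <- cx$a * stats::plogis(-gamma * (cx$dl - s)) +
        (1 - cx$a) * stats::plogis(-gamma * (cx$dr - s))
      k <- exp(-cx$sq[[1]] * inv2e2) + exp(-cx$sq[[2]] * inv2e2) +
        exp(-cx$sq[[3]] * inv2e2) + exp(-cx$sq[[4]] * inv2e2) +
        exp(-cx$sq[[5]] * inv2e2)
      k <- sweep(k, 2, colSums(k), "/")
      p <- k %*% comb
      cs <- colSums(p)
      zero <- cs <= 0  # similarity underflowed everywhere: uniform fallback
      if (any(zero)) {
        p[, zero] <- 1
        cs[zero] <- nrow(p)
      }
      p <- sweep(p, 2, cs, "/")
      ll <- ll + sum(cx$counts * log(pmax(p, floor)))
    }
    ll
  }
  attr(f, "n_trials") <- n_trials
  f
}

#' Log-likelihood of responses under the model
#'
#' Sum over trials of the log PMV probability of the observed response,
#' with each response assigned to its nearest polar bin (circular distance,
#' ties toward the lower bin) and the PMV floored at a tiny probability
#' before taking logs so single outliers cannot produce `-Inf`.
#'
#' @param responses Response tibble (`target_lat`, `target_pol`,
#'   `response_pol`).
#' @param templates A [template_set()].
#' @param params A [model_params()].
#' @param scheme A [weighting_scheme()].
#' @param lateral_range Open interval of lateral angles (deg) of responses
#'   to include; default the median-plane range `(-10, 10)`.
#' @param phi_scale Binaural weighting scale (deg).
#' @param floor PMV probability floor applied before the log.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(responses, templates, params, scheme,
                           lateral_range = c(-10, 10), phi_scale = 13,
                           floor = 1e-9) {
  f <- make_loglik(responses, templates, scheme, lateral_range, phi_scale,
                   floor)
  f(params$gamma, params$s, params$epsilon)
}

#' Log-likelihood of the uniform null model
#'
#' A null listener responding uniformly at random over the `k` polar bins
#' has log-likelihood `n * log(1/k)` regardless of the responses.
#'
#' @param n Number of trials.
#' @param n_bins Number of polar response bins.
#' @return Scalar.
#' @export
null_log_likelihood <- function(n, n_bins) n * log(1 / n_bins)

#' Maximum-likelihood fit of the model parameters for one listener
#'
#' Bounded maximization of [log_likelihood()] over `{gamma, s, epsilon}` by
#' multi-start quasi-Newton search (`L-BFGS-B`) on a transformed unit cube
#' (`gamma` on a log scale), with deterministic seeded start points. The
#' best of all starts is returned together with boundary-convergence flags.
#'
#' @inheritParams log_likelihood
#' @param bounds A [fit_bounds()].
#' @param seed Integer seed for the start points.
#' @param n_starts Number of start points (first start is the cube center).
#' @param boundary_tol Fraction of each parameter range within which a
#'   fitted value counts as stuck at a bound (see [check_convergence()]).
#' @return An object of class `sagloc_fit`: fitted [model_params()],
#'   `log_likelihood`, `n_trials`, per-parameter `boundary_flags`, a
#'   per-start trace, and bookkeeping fields. Supports [generics::tidy()]
#'   and [generics::glance()].
#' @export
fit_subject <- function(responses, templates, scheme, bounds = fit_bounds(),
                        seed = 1, n_starts = 5, lateral_range = c(-10, 10),
                        phi_scale = 13, floor = 1e-9, boundary_tol = 0.01) {
  f <- make_loglik(responses, templates, scheme, lateral_range, phi_scale,
                   floor)
  lg <- log(bounds$gamma)
  from_u <- function(u) list(
    gamma   = exp(lg[1] + u[1] * (lg[2] - lg[1])),
    s       = bounds$s[1] + u[2] * diff(bounds$s),
    epsilon = bounds$epsilon[1] + u[3] * diff(bounds$epsilon))
  nll <- function(u) {
    p <- from_u(u)
    -f(p$gamma, p$s, p$epsilon)
  }
  # cube center, a start in the plausible human range, then seeded random
  interior <- c((log(5) - lg[1]) / (lg[2] - lg[1]),
                (0.5 - bounds$s[1]) / diff(bounds$s),
                (13 - bounds$epsilon[1]) / diff(bounds$epsilon))
  starts <- rbind(rep(0.5, 3), interior,
                  withr::with_seed(seed,
                                   matrix(stats::runif(3 * max(n_starts - 2, 0)),
                                          ncol = 3)))
  one_run <- function(u0) {
    tryCatch(
      stats::optim(u0, nll, method = "L-BFGS-B", lower = 0, upper = 1,
                   control = list(maxit = 300, factr = 1e7)),
      error = function(e) list(par = u0, value = nll(u0), convergence = 99,
                               message = conditionMessage(e)))
  }
  runs <- apply(starts, 1, one_run)
  vals <- vapply(runs, `[[`, numeric(1), "value")
  conv <- vapply(runs, `[[`, numeric(1), "convergence")
  best <- runs[[which.min(vals)]]
  # a cleanly converged start that matches the best value is preferred; an
  # abnormal line-search exit at the same optimum is not a failure
  if (any(conv == 0)) {
    clean <- which(conv == 0)
    best_clean <- runs[[clean[which.min(vals[clean])]]]
    if (best_clean$value <= best$value + 0.01) best <- best_clean
  }
  if (best$convergence != 0) {
    polish <- one_run(best$par)
    if (polish$convergence == 0 && polish$value <= best$value + 1e-6)
      best <- polish
  }
  params <- do.call(model_params, from_u(best$par))
  fit <- structure(list(
    params = params,
    log_likelihood = -best$value,
    n_trials = attr(f, "n_trials"),
    bounds = bounds,
    scheme_name = attr(scheme, "scheme_name"),
    subject_id = if (nrow(responses)) responses$subject_id[1] else NA_character_,
    optimizer_ok = best$convergence == 0,
    trace = tibble::tibble(start = seq_along(runs),
                           neg_loglik = vals,
                           convergence = conv),
    seed = seed), class = "sagloc_fit")
  fit$boundary_flags <- check_convergence(fit, bounds, boundary_tol)
  fit
}

#' Boundary-convergence check
#'
#' Flags each fitted parameter that landed within `tol` of either bound
#' (measured as a fraction of the parameter's range). A flagged parameter
#' means the optimization did not converge within the plausible bounds;
#' such subjects are excluded from model comparisons, regardless of their
#' likelihood.
#'
#' @param fit A `sagloc_fit` (or a [model_params()]).
#' @param bounds A [fit_bounds()].
#' @param tol Fraction of the range counting as "at the bound".
#' @return Named logical vector over `gamma`, `s`, `epsilon`.
#' @export
check_convergence <- function(fit, bounds = fit_bounds(), tol = 0.01) {
  p <- if (inherits(fit, "sagloc_fit")) fit$params else fit
  at_bound <- function(x, b) {
    r <- diff(b)
    x <= b[1] + tol * r || x >= b[2] - tol * r
  }
  c(gamma   = at_bound(p$gamma, bounds$gamma),
    s       = at_bound(p$s, bounds$s),
    epsilon = at_bound(p$epsilon, bounds$epsilon))
}

#' @export
print.sagloc_fit <- function(x, ...) {
  cat(sprintf(
    "<sagloc_fit> subject %s, scheme %s: gamma %.3g, s %.3g, epsilon %.3g deg\n  logL %.2f over %d trials%s\n",
    x$subject_id, x$scheme_name, x$params$gamma, x$params$s,
    x$params$epsilon, x$log_likelihood, x$n_trials,
    if (any(x$boundary_flags)) paste0("  [at bound: ",
      paste(names(which(x$boundary_flags)), collapse = ", "), "]") else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy sagloc_fit
#' @export
tidy.sagloc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("gamma", "s", "epsilon"),
    estimate = c(x$params$gamma, x$params$s, x$params$epsilon),
    lower = vapply(x$bounds, `[`, numeric(1), 1),
    upper = vapply(x$bounds, `[`, numeric(1), 2),
    at_boundary = unname(x$boundary_flags))
}

#' @method glance sagloc_fit
#' @export
glance.sagloc_fit <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id, scheme = x$scheme_name,
                 log_likelihood = x$log_likelihood, n_trials = x$n_trials,
                 bic = bic(x$log_likelihood, x$n_trials),
                 converged = !any(x$boundary_flags) && x$optimizer_ok)
}

#' Fit every listener under every model variant
#'
#' Runs [fit_subject()] for each listener in a cohort under each weighting
#' scheme and collects the results into a fit ledger.
#'
#' @param cohort A [make_cohort()] result (or any list with `listeners` and
#'   `responses`).
#' @param schemes Named list of [weighting_scheme()] objects (one model
#'   variant each); by default the five [standard_schemes()].
#' @param ... Passed to [fit_subject()].
#' @param seed Base seed; each subject-variant fit derives its own.
#' @return A tibble ledger (subject, variant, parameters, logL, n, BIC,
#'   boundary flags) with the fit objects in attribute `fits`.
#' @export
fit_cohort <- function(cohort, schemes = NULL, seed = 1, ...) {
  if (is.null(schemes))
    schemes <- standard_schemes(cohort$listeners, cohort$listeners[[1]]$grid)
  resp <- split(cohort$responses, cohort$responses$subject_id)
  fits <- list()
  rows <- list()
  for (i in seq_along(cohort$listeners)) {
    tpl <- cohort$listeners[[i]]
    rr <- resp[[tpl$subject_id]]
    for (v in names(schemes)) {
      ft <- fit_subject(rr, tpl, schemes[[v]],
                        seed = seed + 7919L * i + match(v, names(schemes)),
                        ...)
      fits[[paste(tpl$subject_id, v)]] <- ft
      rows[[paste(tpl$subject_id, v)]] <- tibble::tibble(
        subject_id = tpl$subject_id, variant = v,
        gamma = ft$params$gamma, s = ft$params$s,
        epsilon = ft$params$epsilon,
        log_likelihood = ft$log_likelihood, n_trials = ft$n_trials,
        bic = bic(ft$log_likelihood, ft$n_trials),
        flag_gamma = ft$boundary_flags[["gamma"]],
        flag_s = ft$boundary_flags[["s"]],
        flag_epsilon = ft$boundary_flags[["epsilon"]],
        converged = !any(ft$boundary_flags) && ft$optimizer_ok)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  out
}
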