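#' Bayesian information criterion
#'
#' `BIC = rho * log(n) - 2 * logL`, with `rho = 3` free parameters for every
#' model variant considered here.
#'
#' @param log_likelihood Maximized log-likelihood.
#' @param n Number of trials.
#' @param rho Number of fitted parameters.
#' @return Scalar (vectorized over its arguments).
#' @export
bic <- function(log_likelihood, n, rho = 3) {
  stopifnot(all(n >= 1))
  rho * log(n) - 2 * log_likelihood
}

#' Evidence table from a fit ledger
#'
#' Keeps complete rows only: any subject with a boundary-flagged (or failed)
#' fit for any variant is excluded from the comparison — subjects are
#' excluded for non-convergence within the plausible bounds, never for low
#' likelihood.
#'
#' @param ledger A [fit_cohort()] ledger.
#' @return Tibble (`subject_id`, `variant`, `log_likelihood`, `n_trials`,
#'   `bic`) restricted to subjects with all variants converged; excluded
#'   subjects are listed in attribute `excluded`.
#' @export
evidence_table <- function(ledger) {
  bad <- unique(ledger$subject_id[!ledger$converged])
  out <- ledger[!ledger$subject_id %in% bad,
                c("subject_id", "variant", "log_likelihood", "n_trials", "bic")]
  attr(out, "excluded") <- bad
  out
}

#' Per-subject posterior probabilities over model variants
#'
#' Default (`mode = "standard"`): posterior proportional to
#' `exp(-BIC / 2)`, the standard BIC approximation to model evidence under
#' equal model priors. `mode = "printed_ratio"` instead normalizes the raw
#' BIC values themselves, `p_k = BIC_k / sum_m BIC_m`; this variant assigns
#' the larger posterior to the larger (worse) BIC and is provided only as a
#' documented compatibility mode.
#'
#' @param evidence An [evidence_table()] (columns `subject_id`, `variant`,
#'   `bic`).
#' @param mode `"standard"` or `"printed_ratio"`.
#' @return Tibble (`subject_id`, `variant`, `posterior`) with posteriors
#'   summing to 1 within each subject.
#' @export
subject_posteriors <- function(evidence, mode = c("standard", "printed_ratio")) {
  mode <- match.arg(mode)
  if (length(unique(evidence$variant)) < 2)
    stop("need at least 2 model variants", call. = FALSE)
  dplyr::mutate(
    dplyr::group_by(evidence, .data$subject_id),
    posterior = if (mode == "standard") {
      e <- exp(-0.5 * (.data$bic - min(.data$bic)))
      e / sum(e)
    } else {
      .data$bic / sum(.data$bic)
    })[, c("subject_id", "variant", "posterior")]
}

posterior_matrix <- function(posteriors) {
  wide <- tidyr::pivot_wider(posteriors, id_cols = "subject_id",
                             names_from = "variant",
                             values_from = "posterior")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$subject_id
  m
}

#' Random-effects Bayesian group model selection
#'
#' Treats the model variant as a random effect varying across subjects.
#' Group model frequencies get a Dirichlet prior (`alpha0` per variant) and
#' are estimated by the standard variational update alternating subject-level
#' attributions with Dirichlet parameter updates (Stephan et al. 2009).
#' Exceedance probabilities `EP_k` (probability that variant `k` is the most
#' frequent in the population) are computed by Monte-Carlo sampling of the
#' Dirichlet posterior. The Bayesian omnibus risk `BOR` is the posterior
#' probability of the null model in which all frequencies are equal, computed
#' from the free energies of the two models (Rigoux et al. 2014), and the
#' protected exceedance probability is
#' `PXP_k = EP_k * (1 - BOR) + BOR / M`.
#'
#' @param posteriors Per-subject variant posteriors: a long tibble from
#'   [subject_posteriors()] or a numeric matrix (subjects x variants, rows
#'   summing to 1).
#' @param n_samples Dirichlet Monte-Carlo sample count for the EPs.
#' @param seed Seed for the EP sampling.
#' @param alpha0 Dirichlet prior count per variant.
#' @param tol,max_iter Convergence control for the variational updates.
#' @return An object of class `rfx_result` with fields `alpha` (posterior
#'   Dirichlet counts), `expected_freq`, `ep`, `bor`, `pxp`, `attribution`
#'   (subject x variant responsibilities), and free energies `f_rfx`,
#'   `f_null`. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
rfx_group_inference <- function(posteriors, n_samples = 1e6, seed = 1,
                                alpha0 = 1, tol = 1e-8, max_iter = 500) {
  p <- if (is.matrix(posteriors)) posteriors else posterior_matrix(posteriors)
  if (nrow(p) < 2 || ncol(p) < 2)
    stop("need at least 2 subjects and 2 variants", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(abs(rowSums(p) - 1) > 1e-6))
    stop("degenerate subject posteriors", call. = FALSE)
  k <- ncol(p)
  n <- nrow(p)
  lme <- log(pmax(p, 1e-12))  # relative log-evidence per subject
  a <- rep(alpha0, k)
  g <- matrix(1 / k, n, k)
  for (it in seq_len(max_iter)) {
    eln <- digamma(a) - digamma(sum(a))
    u <- sweep(lme, 2, eln, "+")
    u <- exp(u - apply(u, 1, max))
    g_new <- u / rowSums(u)
    a_new <- alpha0 + colSums(g_new)
    if (max(abs(a_new - a)) < tol) {
      a <- a_new; g <- g_new; break
    }
    a <- a_new; g <- g_new
  }
  eln <- digamma(a) - digamma(sum(a))
  # variational free energy of the random-effects model
  f_rfx <- sum(g * (lme + rep(eln, each = n) - log(pmax(g, 1e-300)))) +
    lgamma(k * alpha0) - k * lgamma(alpha0) + sum((alpha0 - 1) * eln) -
    (lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * eln))
  # free energy of the null model: frequencies fixed and equal
  f_null <- sum(apply(lme, 1, function(r) {
    m <- max(r); m + log(sum(exp(r - m)))
  })) - n * log(k)
  bor <- 1 / (1 + exp(f_rfx - f_null))
  ep <- withr::with_seed(seed, {
    sm <- matrix(stats::rgamma(n_samples * k, shape = rep(a, each = n_samples)),
                 nrow = n_samples)
    tabulate(max.col(sm, ties.method = "first"), nbins = k) / n_samples
  })
  pxp <- ep * (1 - bor) + bor / k
  structure(list(models = colnames(p) %||% paste0("M", seq_len(k)),
                 alpha = a, expected_freq = a / sum(a), ep = ep, bor = bor,
                 pxp = pxp, attribution = g, f_rfx = f_rfx, f_null = f_null,
                 n_subjects = n, n_samples = n_samples, seed = seed),
            class = "rfx_result")
}

#' @export
print.rfx_result <- function(x, ...) {
  cat(sprintf("<rfx_result> %d subjects, %d variants; BOR = %.3g\n",
              x$n_subjects, length(x$models), x$bor))
  print(tidy(x))
  invisible(x)
}

#' @method tidy rfx_result
#' @export
tidy.rfx_result <- function(x, ...) {
  tibble::tibble(variant = x$models, expected_freq = x$expected_freq,
                 ep = x$ep, pxp = x$pxp)
}

#' @method glance rfx_result
#' @export
glance.rfx_result <- function(x, ...) {
  tibble::tibble(bor = x$bor, n_subjects = x$n_subjects,
                 n_variants = length(x$models),
                 best_variant = x$models[which.max(x$pxp)],
                 f_rfx = x$f_rfx, f_null = x$f_null)
}

#' Nagelkerke goodness of fit from log-likelihoods
#'
#' `R2 = 1 - exp(-(2/n) (logL - logL0))` against the uniform-response null
#' model, rescaled to `R2bar = R2 / (1 - exp((2/n) logL0))` so a perfect
#' discrete predictor attains exactly 1.
#'
#' @param log_likelihood Model log-likelihood (vectorized).
#' @param null_log_likelihood Null-model log-likelihood (see
#'   [null_log_likelihood()]).
#' @param n Number of trials.
#' @return Tibble with columns `r2` and `r2bar`.
#' @export
nagelkerke_r2 <- function(log_likelihood, null_log_likelihood, n) {
  stopifnot(all(n >= 1))
  r2 <- 1 - exp(-(2 / n) * (log_likelihood - null_log_likelihood))
  tibble::tibble(r2 = r2,
                 r2bar = r2 / (1 - exp((2 / n) * null_log_likelihood)))
}

#' End-to-end model variant selection on a fit ledger
#'
#' Convenience wrapper: exclusion of unconverged subjects, per-subject BIC
#' posteriors, and random-effects group inference.
#'
#' @param ledger A [fit_cohort()] ledger.
#' @param ... Passed to [rfx_group_inference()].
#' @inheritParams subject_posteriors
#' @return An `rfx_result` (excluded subjects in attribute `excluded`).
#' @export
select_variants <- function(ledger, mode = "standard", ...) {
  ev <- evidence_table(ledger)
  res <- rfx_group_inference(subject_posteriors(ev, mode), ...)
  attr(res, "excluded") <- attr(ev, "excluded")
  res
}
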