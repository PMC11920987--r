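test_that("synthetic DTFs place the main notch as specified", {
  spec <- synthetic_listener_spec(ear_notch_offset_oct = 0,
                                  spectral_jitter_sd = 0, rng_seed = 9)
  set <- make_dtf_set(spec)
  p <- set$dtf$planes[["0"]]
  freq <- set$dtf$freq_hz
  # deepest point of the spectrum at theta = -30 sits at the start frequency
  i30 <- which(p$theta == -30)
  expect_equal(freq[which.min(p$left_db[i30, ])], spec$notch_start_freq,
               tolerance = 0.02)
  # notch center rises monotonically over the frontal range
  front <- which(p$theta >= -90 & p$theta <= 90)
  centers <- vapply(front, function(i) freq[which.min(p$left_db[i, ])],
                    numeric(1))
  expect_true(all(diff(centers) > 0))
})

test_that("listener generation is deterministic in its seed", {
  a <- make_dtf_set(synthetic_listener_spec(rng_seed = 5))
  b <- make_dtf_set(synthetic_listener_spec(rng_seed = 5))
  c <- make_dtf_set(synthetic_listener_spec(rng_seed = 6))
  expect_identical(a$dtf$planes[["0"]]$left_db, b$dtf$planes[["0"]]$left_db)
  expect_identical(a$templates$planes[["0"]]$left,
                   b$templates$planes[["0"]]$left)
  expect_false(identical(a$dtf$planes[["0"]]$left_db,
                         c$dtf$planes[["0"]]$left_db))
})

test_that("a trajectory outside the band range is rejected", {
  expect_error(
    make_dtf_set(synthetic_listener_spec(notch_start_freq = 12000,
                                         notch_octaves_per_90deg = 1.5)),
    "band range")
})

test_that("a precise listener yields near-zero quadrant error", {
  tpl <- test_listener()$templates
  r <- simulate_responses(tpl, scheme_flat(tpl$grid),
                          model_params(30, 0.1, 3), n_total = 1000, seed = 31)
  expect_lt(qe_pe(r)$qe, 2)
})

test_that("response sampling converges to the generating PMV", {
  tpl <- test_listener()$templates
  sch <- scheme_flat(tpl$grid)
  pars <- model_params(6, 0.5, 12.79)
  tg <- tibble::tibble(lat = 0, pol = 30)
  r <- simulate_responses(tpl, sch, pars, tg, n_total = 10000, seed = 13)
  pmv <- predict_pmv(tpl, 0, 30, pars, sch)
  emp <- as.numeric(table(factor(r$response_pol, levels = pmv$polar_deg)))
  emp <- emp / sum(emp)
  expect_lt(0.5 * sum(abs(emp - pmv$prob)), 0.05)  # total variation
  # chi-square goodness of fit on bins with adequate expected counts
  big <- pmv$prob * 10000 >= 5
  counts <- c(emp[big] * 10000, sum(emp[!big]) * 10000)
  probs <- c(pmv$prob[big], sum(pmv$prob[!big]))
  gof <- suppressWarnings(stats::chisq.test(counts, p = probs / sum(probs)))
  expect_gt(gof$p.value, 0.001)
})

test_that("response simulation is reproducible and seed-sensitive", {
  tpl <- test_listener()$templates
  sch <- scheme_flat(tpl$grid)
  pars <- model_params(6, 0.7, 12.79)
  a <- simulate_responses(tpl, sch, pars, n_total = 120, seed = 8)
  b <- simulate_responses(tpl, sch, pars, n_total = 120, seed = 8)
  c <- simulate_responses(tpl, sch, pars, n_total = 120, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a$response_pol, c$response_pol))
  expect_equal(nrow(a), 120)
})

test_that("cohort generation produces valid independent listeners", {
  co <- make_cohort(n_subjects = 3, n_per_subject = 60, seed = 2)
  expect_length(co$listeners, 3)
  expect_equal(nrow(co$truth), 3)
  expect_equal(sort(unique(co$responses$subject_id)), co$truth$subject_id)
  co2 <- make_cohort(n_subjects = 3, n_per_subject = 60, seed = 3)
  expect_false(identical(co$responses$response_pol,
                         co2$responses$response_pol))
  # ground-truth ledger round-trips through CSV serialization
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(co$truth, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(co$truth))
  # self-match holds for each generated listener
  for (tpl in co$listeners) {
    th <- tpl$planes[["0"]]$theta
    m <- sagloc:::pmv_matrix(tpl, tibble::tibble(lat = 0, pol = th),
                             model_params(6, 0.1, 3), scheme_flat(tpl$grid), 0)
    expect_equal(m$theta[apply(m$pmv, 2, which.max)], th)
  }
})
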