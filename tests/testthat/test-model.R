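test_that("distance profile is zero at a perfect match and selects bands", {
  tpl <- toy_templates(n_theta = 10)
  p <- tpl$planes[["0"]]
  sch <- scheme_flat(tpl$grid)
  d <- distance_profile(tpl, p$left[4, ], sch, "left", 0)
  expect_equal(d[4], 0)
  expect_true(all(d >= 0))
  # one-hot weight reduces the metric to a single band's absolute difference
  onehot <- weighting_scheme(c(0, 1, 0, 0), tpl$grid, "sel")
  target <- p$left[7, ]
  d1 <- distance_profile(tpl, target, onehot, "left", 0)
  expect_equal(d1, abs(p$left[, 2] - target[2]), tolerance = 1e-12)
})

test_that("distance profile equals a double-loop oracle", {
  withr::with_seed(21, {
    for (rep in 1:30) {
      tpl <- toy_templates(n_theta = 7, seed = sample.int(1e6, 1))
      w <- weighting_scheme(runif(4), tpl$grid, "r")
      target <- abs(rnorm(4))
      for (ear in c("left", "right")) {
        got <- distance_profile(tpl, target, w, ear, 0)
        m <- tpl$planes[["0"]][[ear]]
        oracle <- numeric(7)
        for (i in 1:7)
          for (b in 1:4)
            oracle[i] <- oracle[i] + abs(m[i, b] - target[b]) * w$weight[b]
        expect_equal(got, oracle, tolerance = 1e-12)
      }
    }
  })
})

test_that("similarity sigmoid has midpoint, saturation and monotone slope", {
  expect_equal(similarity(0.7, 6, 0.7), 0.5)
  expect_equal(similarity(1e6, 6, 0), 0)
  expect_equal(similarity(-1e6, 6, 0), 1)
  d <- seq(0, 5, by = 0.05)
  s1 <- similarity(d, 4, 1.2)
  s2 <- similarity(d, 8, 1.2)
  expect_true(all(abs(s2 - 0.5) >= abs(s1 - 0.5) - 1e-12))
  expect_true(all(diff(similarity(d, 3, 1)) < 0))  # decreasing in d
  expect_error(similarity(1, -2, 0), "gamma")
})

test_that("binaural combination weights the source-side ear", {
  sl <- c(0.9, 0.1, 0.4)
  sr <- c(0.2, 0.8, 0.4)
  expect_equal(binaural_combine(sl, sr, 0), (sl + sr) / 2)
  expect_equal(binaural_weight(0), 0.5)
  # strongly lateral source on the left: left ear dominates
  a <- binaural_weight(80, phi_scale = 13)
  expect_gt(a, 0.95)
  expect_equal(binaural_combine(sl, sr, 80), a * sl + (1 - a) * sr)
  expect_equal(binaural_combine(sl, sl, 37), sl)
})

test_that("sensorimotor smearing is mass-preserving wrapped-Gaussian blur", {
  theta <- seq(-90, 265, by = 5)
  withr::with_seed(2, prof <- runif(72))
  # kernel far narrower than the grid spacing acts as identity
  expect_lt(max(abs(sensorimotor_smear(prof, 0.5, theta) - prof)), 1e-6)
  expect_equal(sum(sensorimotor_smear(prof, 30, theta)), sum(prof),
               tolerance = 1e-12)
  # a delta input reproduces the wrapped-Gaussian kernel itself
  delta <- rep(0, 72); delta[20] <- 1
  sm <- sensorimotor_smear(delta, 12.79, theta)
  wg <- rowSums(sapply(-2:2, function(m)
    exp(-(theta - theta[20] + 360 * m)^2 / (2 * 12.79^2))))
  expect_equal(sm, wg / sum(wg), tolerance = 1e-9)
  expect_error(sensorimotor_smear(prof, -1, theta), "epsilon")
})

test_that("PMV normalization covers uniform, delta and random profiles", {
  theta <- seq(-90, 265, by = 5)
  expect_equal(to_pmv(rep(2, 72), theta)$prob, rep(1 / 72, 72))
  delta <- rep(0, 72); delta[5] <- 3
  expect_equal(to_pmv(delta, theta)$prob[5], 1)
  withr::with_seed(4, {
    for (i in 1:20)
      expect_equal(sum(to_pmv(runif(72), theta)$prob), 1, tolerance = 1e-12)
  })
  expect_error(to_pmv(rep(0, 72), theta), "zero")
})

test_that("forward pass puts the PMV mode at the target and obeys scatter", {
  tpl <- test_listener()$templates
  sch <- scheme_flat(tpl$grid)
  pmv <- predict_pmv(tpl, 0, 30, model_params(6, 0.1, 3), sch)
  expect_s3_class(pmv, "pmv")
  expect_equal(pmv$polar_deg[which.max(pmv$prob)], 30)
  expect_equal(sum(pmv$prob), 1, tolerance = 1e-9)
  # larger sensorimotor scatter means higher response entropy
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  p5 <- predict_pmv(tpl, 0, 30, model_params(6, 0.5, 5), sch)$prob
  p50 <- predict_pmv(tpl, 0, 30, model_params(6, 0.5, 50), sch)$prob
  expect_gt(ent(p50), ent(p5))
})

test_that("sensitivity extremes: high S flattens, low S saturates to softmax", {
  tpl <- test_listener()$templates
  sch <- scheme_flat(tpl$grid)
  mx <- function(S) max(predict_pmv(tpl, 0, 0, model_params(6, S, 12.79),
                                    sch)$prob)
  expect_lt(mx(15), mx(0.5))          # saturated-similarity side is shallow
  expect_equal(mx(15), 1 / 72, tolerance = 1e-6)
  # low-S limit: PMV shape stops depending on S
  p1 <- predict_pmv(tpl, 0, 0, model_params(6, -10, 12.79), sch)$prob
  p2 <- predict_pmv(tpl, 0, 0, model_params(6, -15, 12.79), sch)$prob
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("self-match holds across the whole polar grid of a listener", {
  tpl <- test_listener()$templates
  sch <- scheme_flat(tpl$grid)
  th <- tpl$planes[["0"]]$theta
  m <- sagloc:::pmv_matrix(tpl, tibble::tibble(lat = 0, pol = th),
                           model_params(6, 0.1, 3), sch, 0)
  expect_equal(m$theta[apply(m$pmv, 2, which.max)], th)
  expect_equal(colSums(m$pmv), rep(1, length(th)), tolerance = 1e-9)
})

test_that("selectivity sharpens the pre-smear response profile", {
  tpl <- test_listener()$templates
  sch <- scheme_flat(tpl$grid)
  p <- tpl$planes[["0"]]
  d <- distance_profile(tpl, p$left[which(p$theta == 45), ], sch, "left", 0)
  contrast <- vapply(c(1, 2, 4, 8, 16, 32), function(g) {
    s <- similarity(d, g, 0.5)
    max(s / sum(s))
  }, numeric(1))
  expect_true(all(diff(contrast) >= -1e-12))
})
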