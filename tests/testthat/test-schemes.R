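test_that("flat scheme is uniform over gradient bands", {
  w <- scheme_flat(default_grid)
  expect_equal(nrow(w), 27)
  expect_equal(w$weight, rep(1 / 27, 27))
  w2 <- scheme_flat(default_grid[1:2, ])
  expect_equal(w2$weight, 1)
})

test_that("bump schemes peak at their nominal centers", {
  nr <- scheme_nr(default_grid)
  expect_equal(which.max(nr$weight), which.min(abs(nr$cf_hz - 8000)))
  dt <- scheme_dt(default_grid)
  expect_equal(which.max(dt$weight), which.min(abs(dt$cf_hz - 6000)))
  # infinitely wide bump degenerates to the flat scheme
  wide <- scheme_bump(default_grid, 8000, width_oct = 1e6)
  expect_equal(wide$weight, scheme_flat(default_grid)$weight, tolerance = 1e-6)
  expect_error(scheme_bump(default_grid, 100), "span")
})

test_that("low-pass scheme decays exponentially per octave", {
  lp <- scheme_lp(default_grid, 0.5)
  expect_true(all(diff(lp$weight) < 0))
  # closed form: weight ratio between two bands is (1/2)^(octave distance)
  for (b in c(3, 10, 20)) {
    expect_equal(lp$weight[b] / lp$weight[1],
                 0.5^(log2(lp$cf_hz[b] / lp$cf_hz[1])), tolerance = 1e-12)
  }
  near_flat <- scheme_lp(default_grid, 1 - 1e-7)
  expect_equal(near_flat$weight, scheme_flat(default_grid)$weight,
               tolerance = 1e-6)
  expect_error(scheme_lp(default_grid, 1), "decreasing")
})

test_that("every scheme constructor emits normalized non-negative weights", {
  schemes <- list(scheme_flat(default_grid), scheme_nr(default_grid),
                  scheme_dt(default_grid), scheme_lp(default_grid),
                  scheme_bump(default_grid, 10000, 0.5, 0.2))
  for (w in schemes) {
    expect_equal(sum(w$weight), 1, tolerance = 1e-9)
    expect_true(all(w$weight >= 0))
    expect_equal(nrow(w), nrow(default_grid) - 1)
  }
})

test_that("spatial variance reduces to polar variance for identical ears", {
  tpl <- toy_templates(n_theta = 12, identical_ears = TRUE)
  nu <- spatial_variance(tpl, 0)
  m <- tpl$planes[["0"]]$left
  oracle <- apply(m, 2, function(x) mean((x - mean(x))^2))
  expect_equal(nu$nu, unname(oracle), tolerance = 1e-12)
  # constant templates carry no spatial information
  flat_tpl <- template_set("c", default_grid[1:4, ], list(
    "0" = list(lateral = 0, theta = c(-90, 0, 90, 180),
               left = matrix(2, 4, 3), right = matrix(5, 4, 3))))
  expect_equal(spatial_variance(flat_tpl, 0)$nu, rep(0, 3))
})

test_that("spatial variance matches a loop oracle and is mirror-symmetric", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      tpl <- toy_templates(n_theta = 10, planes = c(-20, 20),
                           seed = sample.int(1e6, 1))
      for (lat in c(20, -20)) {
        a <- 1 / (1 + exp(-lat / 13))  # ipsilateral-ear weight, signed
        nu <- spatial_variance(tpl, lat)
        pk <- tpl$planes[[as.character(lat)]]
        pm <- tpl$planes[[as.character(-lat)]]
        vv <- function(m) {
          out <- numeric(ncol(m))
          for (b in seq_len(ncol(m))) {
            mu <- sum(m[, b]) / nrow(m)
            out[b] <- sum((m[, b] - mu)^2) / nrow(m)
          }
          out
        }
        oracle <- 0.5 * (vv(pk$left) * a + vv(pk$right) * (1 - a) +
                           vv(pm$left) * (1 - a) + vv(pm$right) * a)
        expect_equal(nu$nu, oracle, tolerance = 1e-9)
      }
      # exact symmetry across mirrored planes
      expect_identical(spatial_variance(tpl, 20)$nu,
                       spatial_variance(tpl, -20)$nu)
    }
  })
  expect_error(spatial_variance(toy_templates(planes = 20), 20), "lateral")
})

test_that("SV weights normalize variances and ignore scale", {
  g3 <- default_grid[1:3, ]
  mk_nu <- function(v) structure(tibble::tibble(band = 2:3,
                                                cf_hz = g3$cf_hz[-1], nu = v),
                                 lateral_plane = 0)
  expect_equal(scheme_sv(mk_nu(c(2, 2)), g3)$weight, c(0.5, 0.5))
  g4 <- default_grid[1:4, ]
  mk_nu4 <- function(v) structure(tibble::tibble(band = 2:4,
                                                 cf_hz = g4$cf_hz[-1], nu = v),
                                  lateral_plane = 0)
  expect_equal(scheme_sv(mk_nu4(c(0, 3, 1)), g4)$weight, c(0, 0.75, 0.25))
  expect_equal(scheme_sv(mk_nu4(c(0, 3, 1) * 17.3), g4)$weight,
               c(0, 0.75, 0.25))
  expect_error(scheme_sv(mk_nu(c(0, 0)), g3), "zero")
})

test_that("group averaging of schemes equals the per-band mean", {
  one <- scheme_nr(default_grid)
  expect_equal(scheme_group_average(list(one))$weight, one$weight)
  g3 <- default_grid[1:3, ]
  a <- weighting_scheme(c(1, 0), g3, "SV", "subject")
  b <- weighting_scheme(c(0, 1), g3, "SV", "subject")
  expect_equal(scheme_group_average(list(a, b))$weight, c(0.5, 0.5))
  withr::with_seed(5, {
    subj <- lapply(1:9, function(i)
      weighting_scheme(runif(27), default_grid, "SV", "subject"))
    got <- scheme_group_average(subj)$weight
    oracle <- numeric(27)
    for (s in subj) oracle <- oracle + s$weight / 9
    expect_equal(got, oracle, tolerance = 1e-12)
  })
  expect_error(scheme_group_average(list()), "empty")
})

test_that("group SV weights of synthetic listeners emphasize high bands", {
  listeners <- lapply(1:3, function(i)
    make_dtf_set(synthetic_listener_spec(rng_seed = 200 + i))$templates)
  sv <- standard_schemes(listeners, default_grid)$SV
  expect_gt(which.max(sv$weight), nrow(sv) / 2)
})
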