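# shared fixtures; everything is generated in code, nothing is stored on disk

default_grid <- erb_bands()

# one cached synthetic listener for model-level tests
test_listener <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_dtf_set(synthetic_listener_spec(rng_seed = 101),
                             subject_id = "T01")
    cache
  }
})

# small hand-built template set: n_theta x n_bands PSG matrices per ear/plane
toy_templates <- function(n_theta = 8, grid = default_grid[1:5, ],
                          planes = 0, seed = 1, identical_ears = FALSE) {
  nb <- nrow(grid) - 1
  theta <- seq(-90, 270 - 360 / n_theta, length.out = n_theta)
  withr::with_seed(seed, {
    pl <- lapply(planes, function(lat) {
      left <- matrix(abs(rnorm(n_theta * nb)), n_theta, nb)
      right <- if (identical_ears) left else
        matrix(abs(rnorm(n_theta * nb)), n_theta, nb)
      list(lateral = lat, theta = theta, left = left, right = right)
    })
    names(pl) <- as.character(planes)
    template_set("toy", grid, pl)
  })
}
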