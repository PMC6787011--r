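# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small synthetic landscape with survey points, enough structure for
# module-level tests without the cost of the full default landscape
small_world <- function() {
  cached("small_world", function() {
    cfg <- truth_config(shape = c(250, 250), field_range = 1500, seed = 42)
    land <- make_landscape(cfg)
    suit <- true_suitability(land)
    # detection_scale raised in proportion to the reduced landscape area so
    # the fixture still yields survey-scale presence counts per block
    pts <- simulate_survey(suit, survey_design(detection_scale = 20,
                                               seed = 42))
    list(land = land, suit = suit, pts = pts,
         domain = raster_extent(land$stack$layers[[1]]))
  })
}

# the default-condition landscape used by the scale-effect and parsimony
# checks (shape and generator defaults of truth_config / survey_design)
default_world <- function() {
  cached("default_world", function() {
    cfg <- truth_config(seed = 7)
    land <- make_landscape(cfg)
    suit <- true_suitability(land)
    pts <- simulate_survey(suit, survey_design(seed = 7))
    list(land = land, suit = suit, pts = pts,
         domain = raster_extent(land$stack$layers[[1]]))
  })
}

# small presence/background draw from 1-2 informative predictors
toy_presence_background <- function(seed, n_p = 30, n_b = 120, strength = 1) {
  withr::with_seed(seed, {
    bg <- data.frame(v1 = rnorm(n_b), v2 = runif(n_b, -1, 1))
    w <- exp(strength * bg$v1)
    pres <- bg[sample(n_b, n_p, replace = TRUE, prob = w), , drop = FALSE]
    rownames(pres) <- NULL
    list(presence = pres, background = bg)
  })
}
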