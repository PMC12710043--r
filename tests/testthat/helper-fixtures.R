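# shared fixtures; everything is generated in code at test time

circ_err <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

sphere_model <- function(center = c(0, 0, 384), radius = 150) {
  list(segments = matrix(c(center, center, radius), nrow = 1,
                         dimnames = list(NULL, c("x1", "y1", "z1",
                                                 "x2", "y2", "z2", "r"))))
}

cylinder_model <- function(radius = 30, z0 = 60, z1 = 700) {
  list(segments = matrix(c(0, 0, z0, 0, 0, z1, radius), nrow = 1))
}

# a simple deterministic 6-leaf plant used across tests
demo_spec <- function(n_leaves = 6) {
  plant_spec(n_leaves = n_leaves,
             internode_lengths = rep(55, n_leaves),
             true_azimuths = (20 + cumsum(c(0, rep(c(185, 170),
                                            length.out = n_leaves - 1)))) %% 360,
             true_inclinations = rep(c(40, 50), length.out = n_leaves))
}

# memoized reconstructions so several tests can share the heavy stages
.fixture_env <- new.env(parent = emptyenv())

fixture_recon <- function(seed, resolution = 128) {
  key <- sprintf("recon_%d_%d", seed, resolution)
  if (is.null(.fixture_env[[key]])) {
    spec <- random_plant_spec(seed)
    .fixture_env[[key]] <- simulate_and_measure(spec, resolution = resolution)
  }
  .fixture_env[[key]]
}

fixture_silhouettes <- function(resolution = 96) {
  key <- sprintf("sil_%d", resolution)
  if (is.null(.fixture_env[[key]])) {
    model <- make_plant(demo_spec())
    .fixture_env[[key]] <- render_silhouettes(model, rig_for_grid(resolution))
  }
  .fixture_env[[key]]
}
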