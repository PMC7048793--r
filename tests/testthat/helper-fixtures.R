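# Shared fixtures, built once per test session.

.fx <- new.env(parent = emptyenv())

# a small, fast phantom: 20 mm cube at 0.5 mm voxels, 5 areas
tiny_config <- function(...) {
  defaults <- list(grid_shape = c(40L, 40L, 40L), voxel_size = rep(0.5, 3),
                   n_areas = 5L, cells_per_injection = 1500L, seed = 42L)
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

tiny_template <- function() {
  if (is.null(.fx$tpl)) .fx$tpl <- build_template(tiny_config())
  .fx$tpl
}

tiny_dataset <- function() {
  if (is.null(.fx$dat)) .fx$dat <- phantom_dataset(tiny_config())
  .fx$dat
}

# the default-condition phantom used by the heavier validation tests
default_dataset <- function() {
  if (is.null(.fx$def)) .fx$def <- phantom_dataset(phantom_config(seed = 7L))
  .fx$def
}
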