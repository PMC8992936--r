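# Small shared fixtures, built once per test run.

# coarse phantom for module tests (fits the same anatomy as the default
# spec on a 32^3 grid)
small_spec <- function(...) {
  phantom_spec(grid_shape = c(32, 32, 32), spacing = c(3.4, 3.4, 6.0), ...)
}

.fixture_env <- new.env(parent = emptyenv())

small_phantom <- function() {
  if (is.null(.fixture_env$ph)) .fixture_env$ph <- make_phantom(small_spec())
  .fixture_env$ph
}

full_phantom <- function() {
  if (is.null(.fixture_env$ph96)) .fixture_env$ph96 <- make_phantom(phantom_spec())
  .fixture_env$ph96
}

random_six_dof <- function(t_max = 5, r_max = 3) {
  six_dof(runif(1, -t_max, t_max), runif(1, -t_max, t_max),
          runif(1, -t_max, t_max), runif(1, -r_max, r_max),
          runif(1, -r_max, r_max), runif(1, -r_max, r_max))
}

max_param_diff <- function(a, b) {
  max(abs(as.numeric(a) - as.numeric(b)))
}
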