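# shared fixtures: a default ventricle-circulation model and a memoized
# full study run (used by the acceptance tests and the heavier
# integration checks, computed once per test session)

default_model <- function(T_max = 110, dt = 0.001) {
  list(geom = ventricle_geometry(), params = ho_params(),
       act = active_law(T_max = T_max), circ = circulation_params(dt = dt))
}

# a faster circulation for sweep-style tests (coarser step, identical
# structure); cycle outcomes change by far less than the assertions'
# tolerances
fast_model <- function(T_max = 110) default_model(T_max, dt = 0.002)

.study_cache <- new.env(parent = emptyenv())

cached_study <- function() {
  if (is.null(.study_cache$report))
    .study_cache$report <- suppressWarnings(run_study(study_config()))
  .study_cache$report
}

random_deformation <- function(rng_scale = 0.15) {
  repeat {
    F <- diag(3) + matrix(stats::runif(9, -rng_scale, rng_scale), 3)
    if (det(F) > 0.3) return(F)
  }
}

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
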