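# Shared cache for expensive solver runs: the base-case cycle at the test
# profile is reused across test files instead of being recomputed.
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}

test_config <- function(...) solver_config(profile = "test", ...)

base_flow <- function() {
  cached("base_flow", solve_cycle(reference_geometry(), beat_kinematics(),
                                  test_config(), keep_phases = TRUE))
}

unconfined_flow <- function() {
  cached("unconfined_flow",
         solve_cycle(reference_geometry(),
                     beat_kinematics(presence = "unconfined"), test_config()))
}

confined_flow <- function() {
  cached("confined_flow",
         solve_cycle(reference_geometry(),
                     beat_kinematics(presence = "confined"), test_config()))
}
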