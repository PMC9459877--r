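# shared fixtures, generated once per test run

short_protocol <- function(n_cycles = 50, standing = 30) {
  data.frame(activity = c("standing", "sit_to_stand", "leg_raise", "walking"),
             duration = c(standing, 15, 15, NA),
             n_cycles = c(NA, NA, NA, n_cycles))
}

noise_free <- list(accel_sd = 0, gyro_sd = 0, gyro_bias_sd = 0)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default-noise session + pipeline result, reused across test files
default_sim <- function() cached("default_sim",
  generate_session(short_protocol(), seed = 1))
default_run <- function() cached("default_run",
  suppressMessages(run_pipeline(default_sim()$session)))

# noise-free session with rigid coupling (gain 1, very stiff) and its run
rigid_sim <- function() cached("rigid_sim",
  generate_session(short_protocol(40), seed = 3, noise = noise_free,
                   coupling = fabric_coupling(stiffness = 9000, damping = 20,
                                              gain = 1, noise_sd = 0)))
rigid_run <- function() cached("rigid_run",
  suppressMessages(run_pipeline(rigid_sim()$session)))

# noise-free session with default coupling parameters
nf_sim <- function() cached("nf_sim",
  generate_session(short_protocol(40), seed = 5, noise = noise_free))
nf_run <- function() cached("nf_run",
  suppressMessages(run_pipeline(nf_sim()$session)))

walking_window <- function(sim, trim_start = 3, trim_end = 2) {
  act <- sim$truth$activities
  wk <- act[act$label == "walking", ][1, ]
  t <- sim$truth$body$time
  which(t > wk$start_s + trim_start & t < wk$end_s - trim_end)
}

# uniform random unit quaternion
random_quaternion <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}
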