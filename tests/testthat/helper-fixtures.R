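# Shared fixtures, built once per test run.

default_design <- function() build_run_design(seed = 11L)

default_sequence <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_probe_sf_sequence(default_design(), seed = 11L)
    cache
  }
})

# A small single-condition session: every block carries one label so the
# model that generated the data is exactly the model being fitted.
mono_session <- function(population, n_runs = 3, seed = 21L,
                         condition = "AttendFixation") {
  sched <- build_session_schedule(
    n_runs,
    design_template = build_run_design(conditions = condition, seed = seed),
    seed = seed
  )
  simulate_session(population, sched, seed = seed,
                   models = default_shift_models(), baseline = condition)
}

expect_within <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
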