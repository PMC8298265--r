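# Shared, lazily computed simulation runs.  The expensive coupled and
# stand-alone runs are computed once per test session and reused across
# test files.  Desk-scale resolution for the scenario comparisons:
# dx = 0.2 cm, 4096 steps/cycle (CFL ratio about 0.5), harmonics 256.

.run_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.run_cache[[name]]))
    .run_cache[[name]] <- force(expr)
  .run_cache[[name]]
}

scenario_net <- function() cached("net02", build_network(dx_cm = 0.2))

scenario_run <- function(label) {
  cached(paste0("run_", label), {
    net <- scenario_net()
    suppressWarnings(
      simulate_coupled(net, case_config(label),
                       steps_per_cycle = 4096L, cycles = 10,
                       prerun_cycles = 6, tol = 5e-3, n_harmonics = 256))
  })
}

control_standalone <- function() {
  cached("standalone_control", {
    net <- cached("net01", build_network(dx_cm = 0.1))
    simulate_pulmonary(net, case_config("control"),
                       steps_per_cycle = 8192L, cycles = 12, tol = 2e-4,
                       n_harmonics = 256)
  })
}
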