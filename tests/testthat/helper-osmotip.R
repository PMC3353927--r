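## Shared fixtures: the standard Lilium parameter set and cached runs
## (several tests interrogate the same trajectories).

std_params <- tip_params()

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

baseline_tc <- function() cached_run("baseline",
                                     run(std_params, duration = 2000))

## parameter set for dt-convergence checks: halved step, smoothing
## half-times pinned at their absolute (dt = 0.4) values
half_dt_params <- function() tip_params(dt = 0.2, ht_expansion = 0.2,
                                        ht_turgor = 0.4, ht_sensor = 0.4,
                                        ht_param = 0.2)

## finer-step parameter set for the whole-tube (growing osmotic area) runs
whole_tube_params <- function() tip_params(dt = 0.05, ht_expansion = 0.2,
                                           ht_turgor = 0.4, ht_sensor = 0.4,
                                           ht_param = 0.2)
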