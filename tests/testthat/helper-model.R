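# Shared small objects for the suite. The drug defaults already carry the
# stored metabolic-scaling calibration, so tests can use them directly.

ref_drug <- drug_parameters()

ref_phys <- build_reference_individual(68, "M", 30)

# A coarse, short engine configuration for tests that only need relative
# behaviour, not terminal-phase precision.
fast_config <- pbpk_config(duration_h = 12, output_interval_h = 0.25)

mono_exp_profile <- function(c0 = 100, k = 0.2, tmax = 48, dt = 0.25) {
  tt <- seq(0, tmax, dt)
  tibble::tibble(time_h = tt, conc_ng_ml = c0 * exp(-k * tt))
}
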