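# Shared fixtures: built once per test run, in code.

default_geom <- build_reference_geometry()
default_surr <- fit_all_surrogates(default_geom)
default_pars <- default_mtu_params()
test_protocol <- protocol_config()

# one small reproducible subject for model-level tests
test_subject <- generate_cohort(1, test_protocol, seed = 42)[[1]]

extensor_names <- names(default_surr)[
  vapply(default_surr, `[[`, "", "group") == "extensor"]
flexor_names <- setdiff(names(default_surr), extensor_names)

quick_trial <- function(condition = "NOEXO", box_mass = 15, seed = 3,
                        rate = 100, subject = test_subject, ...) {
  generate_trial(subject, condition, box_mass, test_protocol,
                 default_surr, seed = seed, rate = rate, ...)
}
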