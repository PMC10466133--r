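# shared fixtures, built in code

# reference adult propofol parameter set (matches inst/extdata scenario)
ref_params <- function() {
  pk_params(CL = 1.79, V1 = 6.28, V2 = 25.5, V3 = 273,
            Q2 = 1.75, Q3 = 1.11, ke0 = 0.146)
}

ref_omegas <- function(scale = 1) {
  c(CL = 0.515, V1 = 0.781, V2 = 0.752, V3 = 0.773,
    Q2 = 0.588, Q3 = 0.457) * scale
}

ref_pop <- function(omega_scale = 1, prop = 0.19, add = 0.02) {
  population_model(ref_params(), omegas = ref_omegas(omega_scale),
                   prop = prop, add = add)
}

# fast-equilibrating parameter set for steady-state checks
small_params <- function() {
  pk_params(CL = 1, V1 = 5, V2 = 10, V3 = 20, Q2 = 1, Q3 = 0.8, ke0 = 0.5)
}

# random plausible parameter draw for property tests
random_params <- function() {
  pk_params(CL = runif(1, 0.5, 4), V1 = runif(1, 3, 15),
            V2 = runif(1, 10, 60), V3 = runif(1, 50, 400),
            Q2 = runif(1, 0.5, 3), Q3 = runif(1, 0.3, 2),
            ke0 = runif(1, 0.05, 0.6))
}

scenario_config <- function() {
  load_config(system.file("extdata", "propofol_reference.yaml",
                          package = "isctsim"))
}
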