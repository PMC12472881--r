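# Shared fixtures: parameterizations are deterministic, build them once.
.fixtures <- new.env()

fx <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

p_mouse <- function() fx("p_mouse", function()
  assemble_parameterization("siRNA-1", "mouse"))
p_monkey <- function() fx("p_monkey", function()
  assemble_parameterization("siRNA-3", "monkey"))
p_human <- function() fx("p_human", function()
  assemble_parameterization("siRNA-2", "human"))

# one shared mouse reference simulation (3 mg/kg, 1500 h)
sim_mouse_3 <- function() fx("sim_mouse_3", function()
  simulate_pbpk(p_mouse(), dose_regimen(3), t_end = 1500))

# quick solver settings for fitting-style tests
fast_tol <- list(rtol = 1e-6, atol = 1e-10)
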