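# Shared fixtures: the bundled skin/blood/laser parameter set and small
# helpers.  Everything is built in code; no stored data.

default_tissue <- function(...) tissue_model(...)
default_blood <- function(...) blood_model(...)
default_optics <- function(...) laser_optics(...)

default_groups <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- nondim_groups(tissue_model(), blood_model(),
                                                laser_optics())
    cache
  }
})

# closed-form Gaussian integrals used as independent oracles
erfc_ <- function(x) 2 * stats::pnorm(-sqrt(2) * x)
gauss_int <- sqrt(pi / 8)                 # int_0^inf exp(-2 x^2) dx
gauss_x2_int <- sqrt(pi) / (4 * 2^1.5)    # int_0^inf x^2 exp(-2 x^2) dx
exp_gauss_int <- function(k) sqrt(pi) / 2 * exp(k^2 / 4) * erfc_(k / 2)

run_traj <- function(profile, t_end, coupling = FALSE, tau = 3,
                     optics = laser_optics(), ...) {
  g <- nondim_groups(tissue_model(relaxation_time = tau), blood_model(), optics)
  sys <- assemble_reduced_system(g, optics, profile, coupling = coupling)
  integrate_system(sys, t_end, ...)
}
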