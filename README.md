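# thermoskin

Transient thermomechanical simulation of laser-heated skin: the
two-dimensional hyperbolic (Cattaneo–Vernotte) bioheat equation, coupled to
the axisymmetric thermoelastic displacement equations of a homogeneous skin
layer, reduced to a three degree-of-freedom system by a Galerkin projection
and integrated in time.

It is written for thermal-therapy modelling: predicting the surface
temperature history and tissue displacement under six laser time-profile
families (single pulse, repetitive pulse, repeating-sequence stairs, step,
repetitive ramp, harmonic), with blood perfusion as a distributed sink and a
finite heat-propagation speed set by the thermal relaxation time τ.

## Model in brief

Heat conduction follows the Cattaneo–Vernotte law `q + τ q̇ = −k ∇T`, which
turns the bioheat equation hyperbolic:

    ρc (Ṫ + τ T̈) = k ∇²T + ρ_b c_b G_b (T_b − T) − τ ρ_b c_b G_b Ṫ
                    + Q_L + τ Q̇_L − 𝔅 T₀ (ε̇_kk + τ ε̈_kk)

with thermal-stress modulus `𝔅 = E α_T/(1−2ν)` coupling it both ways to the
Navier displacement equations.  The laser source is separable,
`Q_L = f1(z) f2(t)`, with a double-exponential axial deposition profile over
the optical penetration depth `δ = 1/sqrt(3 μ_a (μ_a + μ_s (1−g)))`.  A
one-term Galerkin basis (Bessel `J1` radially for the radial displacement,
damped cosine and Gaussians otherwise) reduces the PDEs to
`M ẍ + C ẋ + K x = P(t)` for `x = (q11, p11, s11)`, with the free-surface
traction conditions eliminated heuristically.  An independent axisymmetric
finite-difference solver for the uncoupled equation serves as a verification
oracle, including the τ → 0 (Pennes) limit.  See the methods vignette
(`vignettes/thermoskin-methods.Rmd`) for assumptions, numerical choices and
known limitations.

## Worked example

Maximum skin surface temperature for a single 122 kW/m² laser pulse of 15 s,
with the thermoelastic coupling disabled:

```r
library(thermoskin)
res <- run_scenario("table2_15s")
res$metrics$max_T_C          # 53.0281
res$metrics$peak_time_seconds  # 15.0
```

The run starts from body temperature (37 °C) and peaks at 53.0 °C at the end
of the exposure, in the moderate-hyperthermia/ablation range.  Underneath:

```r
g <- nondim_groups(tissue_model(), blood_model(), laser_optics())
g$delta   # 0.004758  optical penetration depth (m)
g$tstar   # 150.9     characteristic diffusion time (s)
```

A full run directory (trajectory, metrics, snapshots, config echo, derived
constants) is written by `run_scenario(config, out_dir = ...)`, or from a
shell via the installed wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "simulate.R", package = "thermoskin"))')" \
  --preset fig9_step --no-coupling --oracle --out run1
```

Custom configurations are flat YAML documents merged over the bundled skin
preset (`inst/extdata/skin_laser_preset.yaml`); see `?scenario_config`.

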