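# rdcell

Hybrid continuum–discrete simulation of biochemical reaction–diffusion
systems coupled to cell agents, in R.

Many spatially organized biological systems — biofilms, microbial
communities, developing tissues — are naturally modeled by combining a
*continuum* description of chemicals diffusing and reacting in a bulk
medium with a *discrete* description of individual cells that take up,
transform and secrete those chemicals. `rdcell` provides that combination
for 2D rectangular domains:

* an arbitrary number of diffusing chemicals
  $\partial_t u_s - D_s \nabla^2 u_s = R_s(u)$, solved with linear
  finite elements (lumped mass, IMEX time stepping: explicit RK4
  reactions at the nodes, implicit diffusion);
* spatially heterogeneous diffusion: the domain splits into labelled
  subdomains, each with its own diffusion coefficients and bulk reaction
  system;
* point-like cell agents with intracellular reaction networks,
  threshold-based division (with conservative partitioning of contents)
  and death, and Hookean spring mechanics;
* bulk–cell coupling through *transport* reactions (mass crosses the
  membrane, conserved via the nodal volume share) and *membrane*
  reactions (one shared rate drives an outer and an inner reaction, no
  exchange);
* a file-based model interface: a whole simulation is a directory of
  plain-text CSV tables plus reaction files in a small grammar
  (`MassActionReaction: 2 U + V -> 3 U ; k = 1.0`), with zeroth-order,
  mass-action (both directions), Michaelis–Menten and user-registered
  rate laws;
* verification analytics: traveling-wave speed measurement against the
  analytic Fisher-KPP front, L² convergence scoring, and linear
  stability analysis (steady state, Hopf point, Turing band) of the
  Schnakenberg system.

Three exemplar models are bundled and can be written as ready-to-run
model directories: `fisher_kpp`, `schnakenberg_oscillation` /
`schnakenberg_pattern`, and the `cooperator_cheater` public-goods cell
model.  See the methods vignette (`vignettes/rdcell-methods.Rmd`) for
the numerical scheme, conventions and parameter choices.

## Worked example

Stability analysis of the Schnakenberg system
($\emptyset \rightleftharpoons U$, $\emptyset \to V$,
$2U + V \to 3U$) at the patterning parameters
$k_1{=}0.1,\ k_{-1}{=}1,\ k_2{=}0.9,\ k_3{=}1,\ D_U{=}1,\ D_V{=}40$,
then a Fisher-KPP invasion run with measured front speed:

```r
library(rdcell)

p <- schnakenberg_params(0.1, 1.0, 0.9, 1.0, D_U = 1, D_V = 40)
schnakenberg_steady_state(p)
#>   U   V
#> 1.0 0.9

hp <- hopf_point(k_minus1 = 2.2, k2 = 1.5, k3 = 1.0)
#> Hopf point: k1 = 0.61, U = 0.96

tb <- turing_band(p)
#> trace = -0.20, det = 1.00, Turing band: q2 in (0.0337, 0.7413)

model <- fisher_kpp_model(width = 60, height = 10, h = 0.5,
                          dt = 0.01, t_end = 40, sampling_interval = 0.5)
traj <- run_simulation(model)
measure_wave_speed(traj)
#> rd_wave_measurement: speed 1.9577 (level 0.5, fitted over t = [16, 31.5])
fisher_profile_score(traj)
#> [1] 0.0168
```

The steady state $(1.0, 0.9)$ is stable without diffusion
(trace < 0, det > 0) but diffusion-driven-unstable on the wavenumber
band $q^2 \in (0.034, 0.741)$, so a noisy start patterns; the measured
invasion-front speed 1.96 sits within 2% of the analytic minimum speed
$c_{\min} = 2\sqrt{rD} = 2$, and the simulated front matches the order-1
analytic profile with an RMS score of 0.017 (cap 0.5).

## Command line

```sh
Rscript inst/cli/rdcell exemplar schnakenberg_pattern --out model_dir
Rscript inst/cli/rdcell run model_dir/config.txt --seed 1 --out out_dir
Rscript inst/cli/rdcell analyze model_dir/config.txt stability
```

`run` writes per-sample node CSVs, summary traces and (with `--vtk`)
a legacy-ASCII VTK series; `analyze` offers `wave_speed`, `stability`,
`summary_traces` and `convergence_grid`.

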