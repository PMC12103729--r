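# koopmanfes

Data-driven modeling and model predictive control (MPC) of **functional
electrical stimulation (FES)** for ankle plantarflexion and dorsiflexion
assistance during gait.

FES restores ankle function after stroke, spinal cord injury or multiple
sclerosis by electrically eliciting contractions of the gastrocnemius
(push-off, stance) and tibialis anterior (toe clearance, swing).  Closing
the loop around it is hard: the FES-actuated ankle is nonlinear
(saturating muscle recruitment, joint stiffness, gravity) and *switched* —
the dynamics change discretely between the stance and swing phases,
detected from the ground reaction force (GRF).  This package implements,
entirely at desk scale, a Koopman-operator route to that problem:

1. **Switched nonlinear ankle simulator** — per phase ζ ∈ {P, D}:

   J<sub>ζ</sub> θ̈ = τ<sub>muscle</sub>(u) + (1−σ)·r(θ)F<sub>GRF</sub>(t) − (bθ̇ + k(θ−θ₀) + mgl·sin θ),

   with piecewise-linear saturating recruitment u → τ, a half-sine GRF
   template acting only in stance (σ = 0), and fixed-step RK4 integration
   at 200 Hz with zero-order-hold inputs.
2. **Koopman lifting / EDMD** — observables Ψ(x) from a dictionary
   (`state`, `custom`, `trig`; optional delay embedding of length L) lift
   the state; per-phase operators are the least-squares fits
   K̃<sub>ζ</sub> = F G⁺ over phase-restricted snapshot pairs, and a
   recovery map C (argmin ‖CΨ − z‖²) returns to state space, giving the
   switched linear predictor

   z<sub>k+1</sub> = (1−σ<sub>k</sub>)(Ã<sub>P</sub> z<sub>k</sub> + B̃<sub>P</sub> u<sub>k</sub><sup>P</sup>) + σ<sub>k</sub>(Ã<sub>D</sub> z<sub>k</sub> + B̃<sub>D</sub> u<sub>k</sub><sup>D</sup>).

   The 13-dimensional `custom` dictionary (linear terms, sin/cos and
   quadratics of the position coordinates, a velocity product, and a
   constant) meets a 0.5° multi-step prediction threshold on held-out
   gait cycles.
3. **Phase-switched MPC** — receding-horizon minimization of
   Σ‖e‖²<sub>Q</sub> + Σ R u² + e<sub>N</sub>ᵀS<sub>ζ</sub>e<sub>N</sub> subject to the switched predictor,
   hard stimulation bounds (10–25 mA plantarflexor, 10–20 mA
   dorsiflexor), a soft ±20° clearance band, and a terminal set;
   S<sub>ζ</sub> solves the per-phase discrete algebraic Riccati equation
   (DARE) and supplies the stabilizing LQR terminal policy.  The solver
   is a projected Barzilai–Borwein gradient method on the condensed
   input-only problem (0.1 s horizon at 200 Hz).
4. **Synthetic gait protocol and studies** — 150 × 200-sample cycles with
   initial states drawn from [−20°, 25°] × [−2, 2] rad/s and 0–30 mA
   input ramps (or randomized 0–50 mA levels), plus pipelines for
   prediction-accuracy studies across dictionaries/embedding lengths and
   closed-loop tracking studies across gait speeds.

See `vignettes/koopman-mpc-ankle.Rmd` for the model, every tunable
parameter with units and defaults, the numerical choices, and known
limitations.

## Worked example

```r
library(koopmanfes)

# 1. Simulate the training protocol: 30 gait cycles at 200 Hz
params  <- ankle_params()
cfg     <- datagen_config(n_cycles = 30, seed = 42)
cycles  <- generate_dataset(cfg, params)

# 2. Fit the switched Koopman predictor on the 13-observable dictionary
dict  <- make_dictionary("custom", embedding_length = 1, state_dim = 4)
model <- fit_koopman(cycles, dict)
print(model)
#> Switched Koopman predictor ('custom' dictionary, L=1, P=13, state dim 4)
#>   snapshot pairs: stance 2370, swing 2370
#>   one-step residuals (operator): P 0.0456, D 0.00925; recovery: 3.51e-05

# 3. Held-out multi-step prediction accuracy (mean over held-out cycles)
report <- run_prediction_study(cycles, dictionaries = c("custom", "state"),
                               embeddings = 1, seed = 7)
#>  dictionary lifted_dim rmse_mean    rmse_sd threshold_pass
#>      custom         13  0.182061 0.05025511           TRUE
#>       state          5  0.356235 0.05504441           TRUE

# 4. Closed-loop set-point tracking with the phase-switched MPC
ctrl_data  <- generate_dataset(datagen_config(n_cycles = 30, seed = 43,
                                              u_mode = "random"), params)
ctrl_model <- fit_koopman(ctrl_data, make_dictionary("custom", 1, state_dim = 2))
study <- run_closed_loop_study(ctrl_model, params, mpc_problem(max_iter = 60),
                               speeds = c(0.1, 0.2, 0.3),
                               cycle_durations = c(4, 3, 2), n_cycles = 2)
#>  speed cycle_duration rmse_pf_mean rmse_df_mean solver_failure_frac
#>    0.1              4     4.548003     4.436072                   0
#>    0.2              3     4.714069     4.662238                   0
#>    0.3              2     5.095844     5.029384                   0
```

Reading the numbers: the custom dictionary predicts held-out ankle motion
with 0.18° RMSE over full gait cycles — under the 0.5° accuracy
threshold and roughly half the raw-state dictionary's error, which is the
point of lifting.  In closed loop the controller tracks the ±15°
per-phase set points within ~4.5–5.1° RMSE (per-cycle transients and the
enforced ≥10 mA stimulation floor dominate), improving monotonically as
the gait slows — the expected ordering across speeds.  No stimulation
bound is ever violated and the solver never fails.

A thin command-line front end wraps the same functions:

```sh
Rscript exec/koopmanfes simulate --out data/ --cycles 30 --seed 42
Rscript exec/koopmanfes train    --data data/ --model model.json
Rscript exec/koopmanfes predict  --data data/ --model model.json
Rscript exec/koopmanfes control  --model model.json --out run.csv
Rscript exec/koopmanfes config   --params ankle_params.yaml
```

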