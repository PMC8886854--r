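# hybridkin

Single-molecule FRET kinetics of RNase H on structural variants of RNA:DNA
hybrids.

RNase H removes the RNA strand of RNA:DNA hybrids — RNA primers of Okazaki
fragments, R-loop hybrids — and its mechanism depends on the structure
flanking the hybrid.  Anchored at a junction bearing a 3′ ssDNA overhang
(3′OJ) it degrades the RNA **processively** 5′→3′ within one binding event,
so the degradation time is independent of enzyme concentration; on
blunt-ended or 5′-overhang hybrids it is a **distributive**,
sequence-nonspecific endoribonuclease that must rebind for every cut, so the
degradation time grows as 1/C.  smFRET resolves all of this one molecule at
a time: a labelled enzyme binding at site *j* produces a characteristic FRET
level *E*ⱼ, dwell times give the binding kinetics, and a doubly-labelled
substrate reports degradation as a monotone FRET ramp.

`hybridkin` is both the **analysis pipeline** and the **simulator** for this
class of experiment:

* continuous-time Markov simulation of binding, bound-state inter-site
  diffusion, and processive or distributive degradation, rendered into
  noisy framed donor/acceptor traces (`simulate_state_path()`,
  `render_trace()`, `simulate_experiment()`);
* a calibrated substrate library (blunt, nicked, 3′/5′-overhang and
  dual-overhang hybrids, product mimics) whose rate constants are solved
  from dissociation-constant targets (`get_substrate()`, `get_preset()`);
* trajectory idealization by fixed thresholds or a Gaussian HMM with
  Viterbi decoding, dwell extraction with censoring (`compute_fret()`,
  `idealize()`, `extract_dwells()`);
* binding statistics: site assignment, transition density plots, binding
  frequencies, and the dwell-time dissociation constant

  K_d = τ̄_unbound / (τ̄_bound · C)

  with per-site partitioning of the unbound time (`assign_sites()`,
  `build_tdp()`, `binding_frequencies()`, `estimate_kd()`);
* degradation kinetics: ramp-based degradation times, noise-adaptive pause
  detection, single-turnover completeness, and the
  processive/distributive verdict from a bootstrap fit of
  t(C) = t₀ + a/C (`measure_degradation_time()`, `detect_pauses()`,
  `completeness_fraction()`, `classify_mode()`);
* a plain-text TSV trace format and JSON results container
  (`write_trace()`, `read_trace()`, `write_results()`).

## Worked example

Simulate a binding assay on the 3′-overhang substrate at its calibration
concentration and recover the two sites' dissociation constants:

```r
library(hybridkin)

get_substrate("3ORDH")
#> <substrate_spec> 3ORDH
#>   segments:  ssDNA_overhang_3p:20 | rna_dna_hybrid:25 | dsDNA:20
#>   junctions: OJ3p@20, CJ@45

preset <- get_preset("3ORDH")
preset
#> <kinetic_preset> 3ORDH  (C_cal = 0.2 nM, processive cleavage)
#>  site E_bound kd_target tau_bound tau_unbound k_off  k_on
#>  OJ3p    0.77       0.8  250.0000          40 0.004 0.125
#>    CJ    0.48       1.8  111.1111          40 0.009 0.125
#>   k_diff = 0.0004874 /s

pl <- binding_pipeline(preset, n_traces = 30, duration = 3600, seed = 42)
estimate_kd(pl$events, "OJ3p", concentration = 0.2)
#> <kd_estimate> site OJ3p: Kd = 0.765 nM (tau_b = 251 s, tau_u = 38.5 s, C = 0.2 nM, n = 276)
estimate_kd(pl$events, "CJ", concentration = 0.2)
#> <kd_estimate> site CJ: Kd = 1.83 nM (tau_b = 103 s, tau_u = 37.7 s, C = 0.2 nM, n = 282)
```

The full pipeline (simulate → render → FRET → idealize → site-labelled
dwells → dwell-time formula) recovers the calibrated targets of 0.8 and
1.8 nM.  Note the estimator is concentration dependent (its analytic value
is k_off/(k_on·C²)); every estimate records the concentration used.

Classify the degradation mechanism of the 5′-overhang substrate from the
concentration dependence of its degradation time:

```r
cls <- classification_pipeline(get_preset("5ORDH"), c(1, 10, 100),
                               n_traces = 20, seed = 42)
cls
#> <mode_classification> verdict: distributive  (t0 = 2.29 s, a = 229 s*nM, 95% CI [157, 320])
cls$per_concentration
#>   concentration    mean        sem  n
#> 1             1 231.510 37.8556934 20
#> 2            10  26.990  2.7386791 20
#> 3           100   2.985  0.3695143 20
```

Mean degradation time falls from ~230 s at 1 nM to ~3 s at 100 nM — the
1/C signature of distributive action (every dissociation costs one
rebinding wait); the same analysis on the 3′-overhang substrate returns a
flat concentration profile and a `processive` verdict.

A thin command-line wrapper over these functions is included:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/hybridkin.R", package="hybridkin"))')" \
    simulate --substrate 3ORDH --mode binding --conc 0.2 --duration 600 \
    --n-traces 20 --seed 7 --out traces/
```

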