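# tccd

Two-color coincidence detection (TCCD) analysis of single-molecule confocal
photon time traces, for the specific quantification of extracellular
vesicles (EVs) — plus a generative simulator of dual-antibody-labeled
vesicle transits so the whole pipeline can be validated without instrument
data.

## The problem and the method

EVs are membrane-bound nanoparticles whose surface markers (tetraspanins
such as CD9/CD63/CD81) mark their cell of origin, but they are rare, small
and mixed with similarly sized unlabeled particles (lipoproteins,
liposomes, protein oligomers), which scattering-based counters such as NTA
cannot tell apart. TCCD solves the specificity problem at the
single-particle level: the same antibody is split into two pools labeled
with spectrally orthogonal fluorophores; an EV carries several marker
copies and so binds both colors, producing *coincident* photon bursts in
the two detection channels as it transits a confocal volume under fast
flow, while free antibody is single-colored and unlabeled particles are
dark.

From per-channel burst counts `n_A`, `n_B` and observed coincidences
`C_obs`, the package computes the chance-coincidence expectation of two
independent streams

    E = n_A * n_B / n_bins,

the chance-corrected coincidence count `C = max(C_obs − E, 0)`, the
association quotient

    Q = C / (n_A + n_B − C),

and the specific event rate `C / T` (coincident transits per second,
proportional to EV concentration at fixed flow). Downstream it provides
OLS calibration of Q to particles/mL, femtomolar conversion, CLSI-style
limits of blank and detection (`mean + 1.645 sd` construction), and an
antibodies-per-vesicle stoichiometry estimator with a correction for the
dual-color selection bias (see the methods vignette,
`vignettes/tccd-methods.Rmd`).

## Worked example

Simulate a 20-s acquisition at 25 EV transits/s (defaults: 0.1 ms bins,
50 free antibodies/s per channel, background 0.3 counts/bin, 3 antibodies
per EV at 44 photons per fluorophore), then run the full analysis:

```r
library(tccd)

cfg <- sim_config(ev_rate = 25, duration = 20, seed = 11L)
sim <- simulate_trace(cfg)
analyze_trace(sim$trace)
#> <coincidence_summary> (event_level, Q variant 'corrected')
#>   n_a = 2107, n_b = 2112, c_obs = 327
#>   chance E = 22.25  ->  corrected C = 304.8
#>   Q = 0.07786; event rate = 15.24 /s over 20 s
```

Of the 327 observed coincident bursts, 22 are expected by chance overlap
of independent events; the corrected count gives 15.2 specific EV
detections per second. (Not every EV transit is dual-colored: with ~3
antibodies per vesicle and an equimolar color mix, about 64% of labeled
EVs carry both colors, so 15.2/s from 25 transits/s is the expected
yield.) Stoichiometry comes from the coincident-burst intensities scaled
by the single-antibody brightness of the single-colored population:

```r
ea <- detect_events(sim$trace, "a")
eb <- detect_events(sim$trace, "b")
tab <- coincident_intensity_table(ea, eb)
nc <- noncoincident_events(ea, eb)
single <- mean(c(single_antibody_intensity(nc$a),
                 single_antibody_intensity(nc$b)))
antibodies_per_ev(tab$total, single)
#> <stoichiometry_estimate> 2.94 antibodies/EV (ztp_corrected; raw ratio 3.82, n = 327)
```

The raw intensity ratio (3.82) is the mean copy number of the
*dual-colored* subpopulation; inverting the color-selection bias recovers
the population mean of ~3. Unit conversions for sensitivity limits:

```r
particles_per_ml_to_femtomolar(c(5.6e5, 5.7e5))
#> [1] 0.9299 0.9465   # i.e. 0.93 and 0.95 fM
```

A thin CLI over the same functions lives at `inst/cli/tccd.R`
(`simulate`, `detect`, `analyze` subcommands; trace CSV in, events CSV or
summary JSON out).

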