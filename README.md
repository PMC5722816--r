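# tafit

Global and target analysis of femtosecond transient-absorption (TA)
spectroscopy data, built around the photophysics of plant light-harvesting
complexes (LHCs) that bind carotenoids. The package is for spectroscopists
who fit pump–probe difference-absorption matrices ΔA(t, λ) with
IRF-convolved compartmental kinetic models: it resolves carotenoid singlet
dark states (S1, hot S1, S\*, and a quencher state S_q), their energy
transfer to and from chlorophylls, and the quenching pathways that shorten
the Chl excited-state lifetime in dissipative antenna conformations. A
companion geometry module analyses carotenoid end-ring dihedral
distributions over structural ensembles.

## The model

ΔA(t, λ) = Σᵢ cᵢ(t) sᵢ(λ), where the concentrations obey
d**c**/dt = K **c** + **j** g(t) with a transfer-rate matrix K (ns⁻¹,
column = source compartment), excitation vector **j**, and a Gaussian
instrument response g(t). The driven system is solved analytically via the
eigendecomposition of K, each mode rendered by the overflow-safe closed
form ½ exp(k²σ²/2 − k(t−μ)) erfc((μ + kσ² − t)/(σ√2)).

* **Global analysis** (`fit_sequential`): a sequential chain in which every
  state decays into the next; yields lifetimes, evolution-associated
  difference spectra (EADS) and the equivalent parallel-model DADS. Spectra
  are eliminated by variable projection, so the optimizer searches only
  lifetimes and IRF parameters (multi-start, seeded, log-parametrized).
* **Target analysis** (`fit_target`): simultaneous fitting of several
  datasets against declared compartmental schemes with species-associated
  difference spectra (SADS) under constraints — per-compartment zero
  wavelength regions, spectra linked across datasets, and rates linked
  across schemes through shared parameter ids.
* **Scheme library** (`load_scheme`): the two published target models for
  the astaxanthin-binding LHC (`fig3b_508`, `fig3d_690`) with printed rate
  constants marked by provenance, plus the pigment-stoichiometry helper
  `unconnected_carotenoids`.
* **Synthetic experiment** (`generate_paper_like`): two 76-channel spectral
  windows (480–610, 590–720 nm), delays to 3.5 ns, 120-fs IRF, 2% white
  noise, with full ground truth attached — every fitting stage is testable
  without downloads.
* **Geometry** (`dihedral`, `angle_distribution`): signed IUPAC ring–chain
  torsions from multi-MODEL PDB ensembles, circular histograms and
  statistics.

## Worked example

Simulate the Chl-excitation experiment, refit it blind with a four-component
sequential scheme, and inspect the recovered lifetimes:

```r
library(tafit)
d   <- generate_paper_like(690, seed = 1, model = "sequential")
fit <- fit_sequential(d$qy, 4, irf_model(0, fwhm = 0.120), seed = 1)
signif(fit$lifetimes, 4)
#> [1]    2.145   29.670  350.600 2505.000
```

The generating lifetimes were 2.2, 30, 350 and 3200 ps. The first
component — 2.15 ps here — is the energy equilibration among the Chl a
pools (excitation at 690 nm prepares the red pool, which transfers
"uphill"); the hundreds-of-ps component is the quenched Chl decay, and the
long-lived tail is weakly constrained by the 3.5-ns window, as expected.
The same refit across ten seeds recovers the equilibration constant with a
median error below 1%.

Target analysis of the paired experiment, with the quencher S_q linked
across excitations (spectrum and decay rate), runs as in
`analysis/03_target_analysis.R`:

```r
fit <- fit_target(datasets, schemes,
                  free = c("Sq_decay", "S1_decay", "S1_to_Chl",
                           "Sstar_decay", "Chla3p_to_Sq"),
                  constraints = cons, seed = 1, n_starts = 2)
fit$rates_table   # rates in ns^-1 with Jacobian standard errors
```

`branching_yields(load_scheme("fig3b_508"))` turns the scheme's rates into
pathway yields (e.g. 35% of S2's decays go directly to the Chl pool:
7000 ns⁻¹ of a 20000 ns⁻¹ total), and
`unconnected_carotenoids(14, 2.37, 3)` returns `3` — with 14 Chls per
monomer and a Chl/Car ratio of 2.37 the complex carries ~6 astaxanthins,
three more than its binding sites.

The numbered scripts under `analysis/` run the whole workflow (simulate →
global analysis → target analysis → yields/stoichiometry → dihedral
distributions), each writing its tables and a reproducibility manifest
under `results/`.

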