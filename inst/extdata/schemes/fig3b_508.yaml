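# Target model for carotenoid (508 nm) excitation of the astaxanthin-binding
# LHC monomer. Rates in ns^-1. provenance "printed" = published rate constant;
# "free" = package default intended to be refined by fitting.
# The S2 state (lifetime defaulted to 50 fs, total 20000 ns^-1) branches into
# hot S1 and S* and transfers to the Chl pool; S1 loses 183 ns^-1 to the
# ground state and transfers 366 ns^-1 to the Chls; the quencher S_q (shared
# parameter id Sq_decay with the 690-nm model) drains the Chl pool. A parallel
# branch (S1u) models astaxanthin unconnected to the Chls, with the
# solution-like S1 lifetime of 5.3 ps; its input share is a free parameter.
name: fig3b_508
excitation: 508
compartments: [S2, hotS1, S1, Sstar, Sq, Chl, S1u]
rates:
- {from: S2, to: hotS1, rate: 6500.0, id: S2_to_hotS1, provenance: free}
- {from: S2, to: Sstar, rate: 6500.0, id: S2_to_Sstar, provenance: free}
- {from: S2, to: Chl, rate: 7000.0, id: S2_to_Chl, provenance: printed}
- {from: hotS1, to: S1, rate: 2882.0, id: hotS1_to_S1, provenance: free}
- {from: hotS1, to: Chl, rate: 3000.0, id: hotS1_to_Chl, provenance: printed}
- {from: S1, to: Chl, rate: 366.0, id: S1_to_Chl, provenance: printed}
- {from: S1, to: GS, rate: 183.0, id: S1_decay, provenance: printed}
- {from: Sstar, to: GS, rate: 133.0, id: Sstar_decay, provenance: printed}
- {from: Chl, to: Sq, rate: 3.0, id: Chl_to_Sq, provenance: free}
- {from: Chl, to: GS, rate: 0.25, id: Chl_decay, provenance: free}
- {from: Sq, to: GS, rate: 84.0, id: Sq_decay, provenance: printed}
- {from: S1u, to: GS, rate: 189.0, id: S1u_decay, provenance: free}
input: {S2: 0.5, S1u: 0.5}
irf: {mu: 0.0, sigma: 0.051}
# Spectral assumptions: the relaxed carotenoid dark states (S1, S*, and the
# unconnected pool) carry no difference-absorption in the Chl Q_y band.
# Without an assumption of this kind only the eigenvalues (total decay
# rates) of the scheme are identifiable; the S1 branching into the Chl pool
# versus the ground state is pinned down by it. S_q and hot S1 (whose
# excited-state absorption extends beyond 700 nm) are left unconstrained.
constraints:
  zero:
  - {compartment: S1, lo: 660.0, hi: 10000.0}
  - {compartment: Sstar, lo: 660.0, hi: 10000.0}
  - {compartment: S1u, lo: 660.0, hi: 10000.0}
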