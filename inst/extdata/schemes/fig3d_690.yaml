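# Target model for Chl (690 nm) excitation of the astaxanthin-binding LHC
# monomer. Rates in ns^-1. Three Chl a pools equilibrate "uphill" (the red
# pool Chla1p is excited preferentially); each pool is quenched by S_q at its
# own rate (printed range 1.59-5.07 ns^-1); a minor fraction forms Chl and
# Car triplets. Triplet SADS are constrained to zero above (Chl T) and below
# (Car T) 630 nm. S_q decay shares parameter id Sq_decay with fig3b_508 so a
# simultaneous fit links the two models.
name: fig3d_690
excitation: 690
compartments: [Chla1p, Chla2p, Chla3p, Sq, ChlT, CarT]
rates:
- {from: Chla1p, to: Chla2p, rate: 350.0, id: Chla1p_to_Chla2p, provenance: free}
- {from: Chla2p, to: Chla1p, rate: 250.0, id: Chla2p_to_Chla1p, provenance: free}
- {from: Chla2p, to: Chla3p, rate: 300.0, id: Chla2p_to_Chla3p, provenance: free}
- {from: Chla3p, to: Chla2p, rate: 150.0, id: Chla3p_to_Chla2p, provenance: free}
- {from: Chla1p, to: Sq, rate: 1.59, id: Chla1p_to_Sq, provenance: printed}
- {from: Chla2p, to: Sq, rate: 3.2, id: Chla2p_to_Sq, provenance: free}
- {from: Chla3p, to: Sq, rate: 5.07, id: Chla3p_to_Sq, provenance: printed}
- {from: Chla1p, to: GS, rate: 0.25, id: Chla1p_decay, provenance: free}
- {from: Chla2p, to: GS, rate: 0.25, id: Chla2p_decay, provenance: free}
- {from: Chla3p, to: GS, rate: 0.25, id: Chla3p_decay, provenance: free}
- {from: Chla1p, to: ChlT, rate: 0.5, id: Chla1p_to_ChlT, provenance: free}
- {from: ChlT, to: CarT, rate: 20.0, id: ChlT_to_CarT, provenance: free}
- {from: ChlT, to: GS, rate: 0.02, id: ChlT_decay, provenance: free}
- {from: CarT, to: GS, rate: 0.15, id: CarT_decay, provenance: free}
- {from: Sq, to: GS, rate: 84.0, id: Sq_decay, provenance: printed}
input: {Chla1p: 0.75, Chla2p: 0.2, Chla3p: 0.05}
irf: {mu: 0.0, sigma: 0.051}
constraints:
  zero:
  - {compartment: ChlT, lo: 630.0, hi: 10000.0}
  - {compartment: CarT, lo: 0.0, hi: 630.0}
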