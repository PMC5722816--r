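# Ring-chain torsion definitions for carotenoid end rings (editable).
# Atom quadruple C5-C6-C7-C8 spans the bond connecting the ring (C5=C6) to
# the polyene chain (C7=C8); the primed set is the other end ring. Which end
# faces the stroma vs the lumen depends on the binding site; the assignments
# below follow the L1/L2 orientation of the plant LHCII crystal structures
# and are an assumption to be edited for other structures or force fields.
# Residue numbers refer to the cofactor numbering of the input PDB.
species	site	side	chain	resid	a1	a2	a3	a4
LUT	L1	stromal	A	620	C5	C6	C7	C8
LUT	L1	lumenal	A	620	C5'	C6'	C7'	C8'
LUT	L2	stromal	A	621	C5'	C6'	C7'	C8'
LUT	L2	lumenal	A	621	C5	C6	C7	C8
AXT	L1	stromal	A	620	C5	C6	C7	C8
AXT	L1	lumenal	A	620	C5'	C6'	C7'	C8'
AXT	L2	stromal	A	621	C5'	C6'	C7'	C8'
AXT	L2	lumenal	A	621	C5	C6	C7	C8
AXT	N1	stromal	A	622	C5	C6	C7	C8
AXT	N1	lumenal	A	622	C5'	C6'	C7'	C8'
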