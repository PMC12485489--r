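# Backbone covalent geometry targets (Engh & Huber style single set).
# kind: bond lengths in Angstrom, angles in degrees. Inter-residue terms
# (C-N, CA-C-N, C-N-CA) belong to the peptide bond and are reported on the
# later residue of the bond. C-O is used by the backbone builder only.
name	kind	ideal	sigma
N-CA	bond	1.459	0.020
CA-C	bond	1.525	0.026
C-N	bond	1.336	0.023
C-O	bond	1.231	0.020
N-CA-C	angle	111.0	2.8
CA-C-N	angle	117.2	2.2
C-N-CA	angle	121.7	2.5
CA-C-O	angle	120.1	2.1
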