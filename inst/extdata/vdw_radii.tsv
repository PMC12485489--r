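# United-atom van der Waals radii (Angstrom). Carbons and nitrogens bearing
# implicit hydrogens are inflated. Lookup order: atom class, then element,
# then the '*' default.
class	radius
C	1.65
CH	1.90
N	1.60
NH	1.70
O	1.50
S	1.85
P	1.80
*	1.80
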