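# Coarse allowed regions for the CA-trace pseudo-dihedral pair
# (mu_in = CA(i-2..i+1), mu_out = CA(i-1..i+2)), degrees. A residue whose
# defined (mu_in, mu_out) falls inside no rectangle is a CA-geometry outlier,
# as is any residue whose CA(i-1)-CA(i)-CA(i+1) pseudo-angle leaves the
# configured [70, 155] window. Helical geometry sits near (+50, +50);
# extended and polyproline-II geometry in the broad negative band near the
# +/-180 wrap; the cross terms admit junctions between the two regimes.
# Replace via config$ca_map_path (e.g. with authentic CaBLAM calls).
region	in_min	in_max	out_min	out_max
helix	20	80	20	80
extended_ppii	-180	-80	-180	-80
extended_wrap_a	150	180	-180	-80
extended_wrap_b	-180	-80	150	180
extended_wrap_c	150	180	150	180
junction_a	20	80	-180	-80
junction_b	-180	-80	20	80
junction_c	20	80	150	180
junction_d	150	180	20	80
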