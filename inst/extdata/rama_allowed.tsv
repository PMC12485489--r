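# Coarse polygonal (rectangular) Ramachandran allowed regions, one row per
# rectangle, keyed by residue class: general, gly, pro, prepro. A (phi, psi)
# point is an outlier for its class iff it falls inside no rectangle of that
# class. Degrees, inclusive bounds. Replace via config$rama_map_path for a
# higher-fidelity table.
class	region	phi_min	phi_max	psi_min	psi_max
general	beta_ppii	-180	-20	60	180
general	beta_wrap	-180	-20	-180	-150
general	alpha	-160	-20	-90	30
general	lalpha	30	100	-10	90
gly	beta_ppii	-180	-20	60	180
gly	beta_wrap	-180	-20	-180	-150
gly	alpha	-160	-20	-90	30
gly	lalpha	30	100	-10	90
gly	beta_mirror	20	180	-180	-60
gly	beta_mirror_wrap	20	180	150	180
gly	alpha_mirror	20	160	-30	90
pro	pro_alpha	-110	-40	-70	30
pro	pro_ppii	-110	-40	100	180
pro	pro_ppii_wrap	-110	-40	-180	-150
prepro	beta_ppii	-180	-20	60	180
prepro	beta_wrap	-180	-20	-180	-150
prepro	alpha	-160	-20	-90	10
prepro	lalpha	30	100	-10	90
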