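# SYNTHETIC liver reference (NOT published values): per-enzyme maximal
# rates and targeted-proteomics concentrations used to anchor catalytic
# constants (kcat = vmax / conc). Replace with a real reference table for
# production analyses.
# units: vmax umol min^-1 (mg total protein)^-1; conc fmol (ug total protein)^-1
enzyme	vmax_umol_min_mg	conc_fmol_ug
CPT1B	0.0005	0.5
CACT_CPT2	0.003	3
VLCAD	0.004	8
LCAD	0.003	6
MCAD	0.005	10
SCAD	0.004	8
HYD_HAD	0.0125	25
MTP	0.0025	10
MCKAT	0.0015	6
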