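# Acetaminophen (APAP) compound profile: physicochemistry, binding,
# distribution, 13-pathway Michaelis-Menten enzyme kinetics and reference
# clearances for intravenous disposition modelling.
# vmax in pmol/min/mg pool protein (microsomal for CYP/UGT, cytosolic for
# SULT); km in uM.  Absorption parameters are carried as metadata only;
# all simulations are IV.

name: acetaminophen
molecular_weight: 151.2     # g/mol
logp: 0.51
pka: 9.46
fu_plasma: 0.82
blood_plasma_ratio: 1
vss_l_per_kg: 0.8
kp_scalar: 1.63             # metadata: not used with a user-input Vss
cl_iv_reference_l_per_h: 19.7
cl_renal_adult_l_per_h: 1.12
active_hepatic_scalar: 1.5

absorption:                 # metadata only (IV simulations)
  model: ADAM
  peff: 12
  ka_per_h: 5.24
  fa: 0.99
  solubility_mg_per_ml: 13.65
  solubility_ph: 8.94

pathways:
  - {pathway: UGT1A1,  vmax: 6654,   km: 5500,  pool: microsomal}
  - {pathway: UGT1A9,  vmax: 11130,  km: 9200,  pool: microsomal}
  - {pathway: UGT2B15, vmax: 37101,  km: 23000, pool: microsomal}
  - {pathway: SULT1A1, vmax: 1549,   km: 2400,  pool: cytosolic}
  - {pathway: SULT1A3, vmax: 231.0,  km: 1500,  pool: cytosolic}
  - {pathway: SULT1E1, vmax: 167.2,  km: 1900,  pool: cytosolic}
  - {pathway: SULT2A1, vmax: 814.1,  km: 3700,  pool: cytosolic}
  - {pathway: CYP1A2,  vmax: 34.5,   km: 220,   pool: microsomal}
  - {pathway: CYP2C9,  vmax: 9.86,   km: 660,   pool: microsomal}
  - {pathway: CYP2C19, vmax: 29.87,  km: 2000,  pool: microsomal}
  - {pathway: CYP2D6,  vmax: 6.57,   km: 440,   pool: microsomal}
  - {pathway: CYP2E1,  vmax: 90.06,  km: 4020,  pool: microsomal}
  - {pathway: CYP3A4,  vmax: 62.13,  km: 130,   pool: microsomal}
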