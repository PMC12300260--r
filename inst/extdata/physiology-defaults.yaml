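# Default age-resolved physiology for the minimal PBPK model.
#
# Every constant here is a published, documented substitute for the
# simulator-internal population machinery used in commercial platforms.
# Sources are indicated per block; values are config entries, not facts
# about any particular virtual population.

adult_age: 20            # years; physiology is age-invariant above this

# Growth anchors (monotone Hermite spline through reference percentile-50
# values; WHO growth standards + CDC charts, rounded).
growth:
  ages:    [0, 0.25, 0.5, 1, 2, 5, 10, 15, 20]
  weights: [3.5, 6.0, 7.5, 10.0, 12.2, 18.3, 32.0, 55.0, 70.0]   # kg
  heights: [50, 60, 67, 75, 87, 110, 138, 167, 175]              # cm

# Liver weight from body surface area (Haycock BSA; Johnson et al. 2005
# liver volume allometry, unit density): liver_g = 722 * BSA^1.176.
liver:
  bsa_coefficient: 722
  bsa_exponent: 1.176

# Hepatic blood flow as allometrically scaled share of cardiac output,
# anchored at 90 L/h for a 70-kg adult (~25% of cardiac output).
hepatic_flow:
  adult_l_per_h: 90
  allometric_exponent: 0.75

# Protein-per-gram-liver scalars.
# MPPGL: Barter et al. 2007 age equation, 10^(1.407 + 0.0158 a - 3.8e-4 a^2
# + 2.4e-6 a^3) mg microsomal protein / g liver (~26 at birth, ~39 adult).
# CPPGL: constant 80 mg cytosolic protein / g liver (no accepted ontogeny).
mppgl:
  log10_coefficients: [1.407, 0.0158, -0.00038, 0.0000024]
cppgl: 80

# Renal maturation: sigmoidal GFR fraction of the adult value vs
# postmenstrual age in weeks (Rhodin et al. 2009: TM50 47.7 weeks, Hill 3.4),
# with postnatal age converted assuming term birth at 40 weeks.
gfr:
  pma_at_birth_weeks: 40
  tm50_weeks: 47.7
  hill: 3.4

# Plasma binding held at adult values across ages (filtration-dominated
# renal clearance and conjugative metabolism; no binding ontogeny applied).
fu_plasma: 0.82
blood_plasma_ratio: 1

# Non-SULT enzyme maturation profiles: fraction-of-adult activity
#   f(age) = f0 + (1 - f0) * age^h / (t50^h + age^h),
# normalised to 1 at the adult reference age.  f0 = fraction at birth,
# t50 = maturation half-time (years).  Values follow published ontogeny
# summaries (UGT pathways maturing over months-years; CYP3A4 low at birth;
# CYP2E1 essentially absent at birth) and are tunable defaults calibrated
# so the model's pathway-contribution fractions match reported
# age-group-level values.
maturation:
  UGT1A1:  {f0: 0.15, t50: 0.4, hill: 1.2}
  UGT1A9:  {f0: 0.10, t50: 1.5, hill: 1.0}
  UGT2B15: {f0: 0.20, t50: 1.0, hill: 1.0}
  CYP1A2:  {f0: 0.03, t50: 1.2, hill: 1.0}
  CYP2C9:  {f0: 0.30, t50: 0.3, hill: 1.0}
  CYP2C19: {f0: 0.20, t50: 0.5, hill: 1.0}
  CYP2D6:  {f0: 0.05, t50: 0.1, hill: 1.0}
  CYP2E1:  {f0: 0.02, t50: 0.4, hill: 1.5}
  CYP3A4:  {f0: 0.10, t50: 0.3, hill: 1.0}

# Inter-individual variability (log-normal, median 1) for virtual cohorts.
variability:
  enzyme_cv: 0.30     # per-pathway intrinsic clearance multipliers
  vss_cv: 0.20        # volume of distribution multiplier
  weight_cv: 0.15     # body weight around the growth-model median
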