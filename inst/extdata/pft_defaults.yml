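# Default plant-functional-type configuration for the reduced-form
# simulator. Bioclimatic limits (degC; growing degree-days above 5 degC)
# gate establishment and survival; the remaining constants parameterize the
# surrogate production, allometry and turnover scheme. These values are
# implementer-chosen defaults, tuned to the package's synthetic zonal
# climatology (see the methods vignette), not published calibrations.
#
# tc_min_est / tc_max_est : 20-yr mean coldest-month window for establishment
# gdd5_min                : minimum 20-yr mean growing degree-days (base 5)
# tw_max                  : 20-yr mean warmest-month survival ceiling
# tc_surv                 : 20-yr mean coldest-month survival floor
# k_allom2                : height = k_allom2 * diameter^k_allom3
# sla                     : specific leaf area, m2 per kgC
# wood_density            : kgC per m3 of stem volume
# maint_resp_coeff        : maintenance respiration per kgC live biomass /yr
# leaf_turnover, root_turnover, sap_turnover : fractional loss per year
pfts:
  TNE:
    name: temperate needleleaved evergreen
    woody: true
    phenology: evergreen
    tc_min_est: -2.0
    tc_max_est: 22.0
    gdd5_min: 900
    tw_max: .inf
    tc_surv: -7.0
    k_allom2: 40.0
    sla: 9.0
    wood_density: 200
    maint_resp_coeff: 0.03
    leaf_turnover: 0.3
    root_turnover: 0.5
    sap_turnover: 0.05
  TBE:
    name: temperate broadleaved evergreen
    woody: true
    phenology: evergreen
    tc_min_est: 3.0
    tc_max_est: 18.8
    gdd5_min: 1200
    tw_max: .inf
    tc_surv: -2.0
    k_allom2: 40.0
    sla: 12.0
    wood_density: 200
    maint_resp_coeff: 0.03
    leaf_turnover: 0.3
    root_turnover: 0.5
    sap_turnover: 0.05
  TBS:
    name: temperate broadleaved summergreen
    woody: true
    phenology: summergreen
    tc_min_est: -17.0
    tc_max_est: 15.5
    gdd5_min: 1200
    tw_max: .inf
    tc_surv: -22.0
    k_allom2: 40.0
    sla: 25.0
    wood_density: 200
    maint_resp_coeff: 0.03
    leaf_turnover: 0.5
    root_turnover: 0.5
    sap_turnover: 0.05
  BNE:
    name: boreal needleleaved evergreen
    woody: true
    phenology: evergreen
    tc_min_est: -32.5
    tc_max_est: -2.0
    gdd5_min: 600
    tw_max: 23.0
    tc_surv: -45.0
    k_allom2: 40.0
    sla: 9.0
    wood_density: 200
    maint_resp_coeff: 0.03
    leaf_turnover: 0.3
    root_turnover: 0.5
    sap_turnover: 0.05
  BSW:
    name: boreal summergreen woody
    woody: true
    phenology: summergreen
    tc_min_est: -45.0
    tc_max_est: -2.0
    gdd5_min: 350
    tw_max: 23.0
    tc_surv: -60.0
    k_allom2: 40.0
    sla: 25.0
    wood_density: 200
    maint_resp_coeff: 0.03
    leaf_turnover: 0.5
    root_turnover: 0.5
    sap_turnover: 0.05
  CPG:
    name: C3 perennial grass
    woody: false
    phenology: grass
    tc_min_est: -.inf
    tc_max_est: 15.5
    gdd5_min: 50
    tw_max: .inf
    tc_surv: -.inf
    k_allom2: .nan
    sla: 35.0
    wood_density: .nan
    maint_resp_coeff: 0.03
    leaf_turnover: 0.5
    root_turnover: 0.5
    sap_turnover: 0.0

# Surrogate-scheme constants shared across PFTs.
constants:
  par_full: 12000        # mol photons /m2/yr under permanent overhead sun
  cloud_attenuation: 0.75
  vcap: 3.0              # carboxylation-capacity ceiling, kgC/m2/yr
  co2_ref: 370           # ppmv at which the CO2 factor equals 1
  co2_half_sat: 400      # ppmv, half-saturation of the CO2 response
  wue_exp: 0.3           # water-use-efficiency exponent on co2/co2_ref
  demand_base: 250       # mm/yr evaporative demand at 0 degC warm season
  demand_per_degC: 20    # mm/yr extra demand per degC of warmest month
  f_temp_scale: 15       # degC ramp width of the temperature response
  heat_mort_rate: 0.3    # extra fractional mortality under heat stress /yr
  bioclim_window: 20     # years in the running climate summary
  sapling_leaf: 0.05     # initial pools of an established sapling, kgC
  sapling_sap: 0.1
  sapling_root: 0.05
  grass_seed_scale: 0.042 # kgC/m2 of grass leaf (and root) establishment
                          # input per unit sapling establishment rate
  alloc_leaf: 0.3        # woody allocation fractions of NPP
  alloc_root: 0.3
  alloc_sap: 0.4
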