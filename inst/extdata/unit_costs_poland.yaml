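# Unit costs and macro parameters, Poland 2015, public-payer + societal view.
# All monetary values EUR; PLN figures were converted at pln_per_eur.
label: poland_2015
pln_per_eur: 4.2624            # average Q4-2015 exchange rate
gdp_per_capita_annual_eur: 10900
macro:                         # inputs of the paid-work unit-cost derivation
  gdp_million_eur: 420164.45   # national GDP, 2015
  employed_thousand: 16234     # employed persons
  max_annual_hours: 2016       # maximum working hours in the year
  labour_elasticity: 0.65      # Cobb-Douglas output elasticity of labour
paid_work_hour_eur: null       # derived from macro when null -> 8.34
care_hour_eur: 5.27            # opportunity-cost wage per hour (average wage)
monthly_working_hours: 168     # average working hours in a month
weeks_per_month: 4.345
days_per_month: 30.44
direct:
  consultation_specialist: 7.57      # W11 first-type gastroenterology consultation
  hospitalisation_one_day: 109.80
  hospitalisation_medical: 975.98    # DRG F58
  hospitalisation_surgical: 1553.16  # DRG F51/F52 weighted by 2014 occurrences
  diagnostics_biologic_month: 54.90
drugs:                         # monthly use = units_per_day x days_per_month
  aminosalicylate:
    unit_label: mesalazine 1.5 g (1 DDD)
    unit_cost_eur: 0.53
    units_per_day: 1.0
  immunosuppressant:
    unit_label: azathioprine 0.15 g (1 DDD)
    unit_cost_eur: 0.37
    units_per_day: 1.0
  glucocorticoid:
    unit_label: prednisone 10 mg (1 DDD)
    unit_cost_eur: 0.24
    units_per_day: 1.0
biologics:                     # 12-month recommended dosing divided by 12
  body_weight_kg: 64.71        # average weight of biologic-treated patients
  adalimumab:
    unit_mg: 80
    unit_cost_eur: 967.01
    mg_year_fixed: 1240        # 160 + 80 induction, then 40 mg every other week
  infliximab:
    unit_mg: 100
    unit_cost_eur: 298.23
    mg_per_kg_dose: 5
    infusions_per_year: 8      # weeks 0, 2, 6, then every 8 weeks
sensitivity:
  unit_cost_basis: gdp_per_worker_labour_share
  # alternative bases; per-hour values must be supplied by the user
  average_wage_hour_eur: null
  gross_value_added_hour_eur: null
expense_ranges_eur: [0.0, 23.5, 46.9, 93.8, 140.8]
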