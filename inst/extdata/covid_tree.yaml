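# COVID-19 antiviral out-patient case study: 10-day one-pill-per-day regimen.
# Constant leaf rates are the NoP-weighted WNARs pooled from six oseltamivir
# adherence studies (see six_studies.csv); the remaining leaves use the
# case-study assumptions: limited healthcare access 1.2E-4/day; prior-
# knowledge deficit starting at 1.5E-4/day and losing 8% of the initial rate
# per elapsed day; ICT and manual delivery subsystems failing at 8.12E-5 and
# 5.34E-5 per day with 4 h and 2 h repair; social support stratified by age
# band with equal cohort weights.
name: COVID-19 antiviral non-adherence case study
top: NA
nodes:
- id: NA
  label: Non-adherence (discontinuation of the regimen)
  kind: top
  gate: OR
  children: [SocRel, PatRel, ConRel, HeaRel, TheRel]
- id: SocRel
  label: Social/economic-related factors
  kind: intermediate
  gate: OR
  children: [SocSup, HeaAcc]
- id: PatRel
  label: Patient-related factors
  kind: intermediate
  gate: OR
  children: [NoMed, Forgot, Other]
- id: ConRel
  label: Condition-related factors
  kind: intermediate
  gate: OR
  children: [NoSym]
- id: HeaRel
  label: Healthcare-system-related factors
  kind: intermediate
  gate: OR
  children: [ClinImp, NoTab, DelSys, PriKno]
- id: DelSys
  label: Medicine delivery system (both channels down)
  kind: intermediate
  gate: AND
  children: [IctSys, ManSys]
- id: TheRel
  label: Therapy-related factors
  kind: intermediate
  gate: OR
  children: [SidEff]
- id: SocSup
  label: Limited social support
  kind: basic
  rate:
    form: age_stratified
    bands:
    - {label: "<25", rate: 4.138e-4, weight: 0.3333333333333333}
    - {label: "25-45", rate: 1.379e-4, weight: 0.3333333333333333}
    - {label: ">45", rate: 2.069e-4, weight: 0.3333333333333334}
- id: HeaAcc
  label: Limited healthcare access
  kind: basic
  rate: {form: constant, rate: 1.2e-4}
- id: NoMed
  label: Choice not to take the medication
  kind: basic
  rate: {form: constant, rate: 3.448e-4}
- id: Forgot
  label: Forgetfulness
  kind: basic
  rate: {form: constant, rate: 4.897e-3}
- id: Other
  label: Other patient-related factors
  kind: basic
  rate: {form: constant, rate: 5.002e-3}
- id: NoSym
  label: No symptoms (asymptomatic course)
  kind: basic
  rate: {form: constant, rate: 5.931e-3}
- id: ClinImp
  label: Clinical improvement
  kind: basic
  rate: {form: constant, rate: 1.379e-4}
- id: NoTab
  label: Limited tablets (2-day resupply delay)
  kind: basic
  rate: {form: constant, rate: 3.448e-4}
- id: PriKno
  label: Lack of prior knowledge of adherence
  kind: basic
  rate: {form: linear_decay, initial_rate: 1.5e-4, decay_fraction_per_day: 0.08}
- id: SidEff
  label: Side effects
  kind: basic
  rate: {form: constant, rate: 8.315e-3}
- id: IctSys
  label: ICT medicine-delivery subsystem
  kind: basic
  rate: {form: repairable, failure_rate: 8.12e-5, mean_repair_time: 4}
- id: ManSys
  label: Manual medicine-delivery subsystem
  kind: basic
  rate: {form: repairable, failure_rate: 5.34e-5, mean_repair_time: 2}
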