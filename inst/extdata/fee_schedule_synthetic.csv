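code,category,unit_cost_tzs,modality,variant,ward
consult_emergency,consult_specialist,20000,,,
consult_surgery,consult_specialist,25000,,,
consult_cardiology,consult_specialist,25000,,,
consult_psychiatry,consult_specialist,22000,,,
consult_urology,consult_specialist,25000,,,
consult_dentist,consult_generalist,15000,,,
consult_gp,consult_generalist,12000,,,
consult_physio,consult_therapy,18000,,,
proc_intubation,procedure_nonsurgical,60000,,,
proc_npa,procedure_nonsurgical,15000,,,
proc_oxygen,procedure_nonsurgical,30000,,,
proc_fluids,procedure_nonsurgical,12000,,,
proc_transfusion,procedure_nonsurgical,80000,,,
surg_debridement,procedure_surgical,120000,,,
surg_external_fixation,procedure_surgical,250000,,,
surg_orif,procedure_surgical,280000,,,
surg_laparotomy,procedure_surgical,260000,,,
surg_craniotomy,procedure_surgical,350000,,,
surg_amputation,procedure_surgical,200000,,,
surg_tracheostomy,procedure_surgical,160000,,,
img_xray_unilateral,imaging,15000,xray,unilateral,
img_xray_bilateral,imaging,25000,xray,bilateral,
img_ct_head,imaging,180000,ct,head,
img_ct_abdomen,imaging,210000,ct,abdomen,
img_mri_brain,imaging,300000,mri,brain,
img_mri_spine,imaging,340000,mri,spine,
img_mri_msk,imaging,280000,mri,msk,
img_uss_abdomen,imaging,35000,uss,abdomen,
img_uss_fast,imaging,30000,uss,fast,
img_uss_doppler,imaging,50000,uss,doppler,
bed_general_shared,admission_day,15000,,,general
bed_icu,admission_day,100000,,,icu
cons_saline,consumable,6000,,,
cons_blood_unit,consumable,45000,,,
cons_dressing,consumable,8000,,,
cons_cannula,consumable,4000,,,
death_certificate,death_expense,10000,,,
morgue_transport,death_expense,15000,,,
body_bag,death_expense,8000,,,
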