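table,column,type,description
patients,patient_id,integer,1-based patient identifier
patients,arm,character,randomized arm: intervention or usual_care
patients,age,numeric,age in years at baseline
patients,sex,character,male or female
patients,smoking_status,character,"current, ex_lt2y (quit < 2 years) or ex_ge2y"
patients,severity,character,airflow limitation: moderate or severe_or_very_severe
patients,site,character,recruiting site label
patients,prior_admission,logical,hospital admission in the previous year
patients,prior_rehab,logical,pulmonary rehabilitation in the previous year
patients,live_in_support,logical,live-in support available
patients,baseline_sgrqc,numeric,baseline SGRQ-C score (0-100; higher = worse)
patients,hr_baseline,numeric,latent mean resting heart rate (bpm)
patients,spo2_baseline,numeric,latent mean oxygen saturation (%)
patients,symptom_propensity,numeric,latent mean per-item diary score (0-3)
patients,salbutamol_baseline,numeric,latent mean reliever use (puffs/day)
daily,patient_id,integer,patient identifier
daily,study_day,integer,1-based day since randomization
daily,completed,logical,whether the day's entry was completed
daily,wellbeing,integer,diary item score 0-3 (empty when not completed)
daily,cough,integer,diary item score 0-3
daily,breathless,integer,diary item score 0-3
daily,sputum_quantity,integer,diary item score 0-3
daily,sputum_colour,integer,diary item score 0-3
daily,symptom_score,integer,sum of the five item scores (0-15)
daily,spo2,numeric,oxygen saturation % (<= 100)
daily,heart_rate,numeric,heart rate in bpm (> 0)
daily,salbutamol_use,integer,reliever puffs taken that day
daily,in_exacerbation,logical,simulator truth: day lies in a latent episode
outcomes,patient_id,integer,patient identifier
outcomes,sgrqc_0,numeric,baseline SGRQ-C (0-100)
outcomes,sgrqc_6,numeric,6-month SGRQ-C (empty after withdrawal/death)
outcomes,sgrqc_12,numeric,12-month SGRQ-C (empty after withdrawal/death)
outcomes,eq5d_change,numeric,change in EQ-5D index baseline to 12 months
outcomes,scl20_change,numeric,change in SCL-20 depression score
outcomes,scl10a_change,numeric,change in SCL-10A anxiety score
outcomes,n_admissions,integer,hospital admissions during follow-up
outcomes,any_admission,logical,at least one admission
outcomes,n_exacerbations,integer,latent exacerbation episodes within follow-up
outcomes,gp_contacts,integer,GP surgery contacts over follow-up
outcomes,nurse_contacts,integer,practice-nurse contacts over follow-up
outcomes,smoking_cessation,logical,reported not smoking at 12 months
outcomes,death,logical,died during follow-up
outcomes,withdrawal_day,integer,withdrawal day (empty if none)
outcomes,followup_days,integer,days of observation (censored at death/withdrawal)
care_events,patient_id,integer,patient identifier
care_events,day,integer,study day of the treated care event
care_events,kind,character,"antibiotics_prescribed, oral_steroids_prescribed, ae_attendance or hospital_admission"
symptom_reports,patient_id,integer,patient identifier
symptom_reports,day,integer,study day of the report
symptom_reports,major_symptoms,character,semicolon-separated major symptoms
symptom_reports,minor_symptoms,character,semicolon-separated minor symptoms
alerts,patient_id,integer,patient identifier
alerts,study_day,integer,day the alert fired
alerts,parameter,character,"heart_rate, symptom_score or spo2"
alerts,observed,numeric,observed value that crossed the threshold
alerts,threshold,numeric,threshold in force that day
alerts,direction,character,above (HR/symptoms) or below (SpO2)
review_queue,patient_id,integer,patient identifier
review_queue,review_day,integer,day of the review
review_queue,alert_count_14d,integer,alerts in the trailing 14 days
review_queue,data_received,logical,any completed entry in the window
review_queue,rank,integer,review priority (1 = first)
exacerbations,patient_id,integer,patient identifier
exacerbations,start_day,integer,event start day
exacerbations,trigger,character,care_event_with_symptoms or salbutamol_48h
tte,patient_id,integer,patient identifier
tte,time,integer,days to first exacerbation or censoring
tte,observed,logical,FALSE when censored at end of follow-up
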