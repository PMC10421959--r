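step,term_id
prevalence,hives
prevalence,sensitivity_to_sunlight
prevalence,radiation_skin_reaction
prevalence,nail_discoloration
prevalence,skin_darkening
prevalence,stretch_marks
prevalence,nail_loss
prevalence,bed_pressure_sores
prevalence,painful_urination
prevalence,irregular_periods_vaginal_bleeding
prevalence,missed_expected_menstrual_period
prevalence,ejaculation
prevalence,unable_to_have_orgasm
prevalence,pain_with_sexual_intercourse
prevalence,delayed_orgasm
prevalence,breast_swelling_and_tenderness
prevalence,decreased_sweating
prevalence,flashing_lights
severity,blurred_vision
severity,body_odor
severity,chills
severity,concentration
severity,cracking_at_corners_of_mouth
severity,dizziness
severity,heart_palpitations
severity,hiccups
severity,memory
severity,nosebleed
severity,watery_eyes
severity,wheezing
interference,urinary_frequency
interference,urinary_urgency
interference,mouth_throat_sores
interference,fecal_incontinence
interference,headache
amount,hair_loss
reliability,acne
reliability,anxious
reliability,change_in_usual_urine_color
reliability,constipation
reliability,dry_mouth
reliability,general_pain
reliability,pain_and_swelling_at_injection_site
physician,achieve_and_maintain_erection
physician,bloating
physician,bruising
physician,decreased_libido
physician,discouraged
physician,gas
physician,hoarseness
physician,hot_flashes
physician,increased_sweating
physician,nail_ridging
physician,vaginal_discharge
physician,vaginal_dryness
physician,voice_quality_changes
reintroduced,anxious
reintroduced,constipation
reintroduced,dizziness
reintroduced,general_pain
reintroduced,headache
reintroduced,mouth_throat_sores
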