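metric,term_id,value_percent
prevalence,hives,4.7
prevalence,sensitivity_to_sunlight,4.0
prevalence,radiation_skin_reaction,3.6
prevalence,nail_discoloration,2.8
prevalence,skin_darkening,2.5
prevalence,stretch_marks,2.5
prevalence,nail_loss,1.0
prevalence,bed_pressure_sores,0.8
prevalence,painful_urination,3.4
prevalence,irregular_periods_vaginal_bleeding,1.3
prevalence,missed_expected_menstrual_period,1.3
prevalence,ejaculation,4.2
prevalence,unable_to_have_orgasm,3.0
prevalence,pain_with_sexual_intercourse,3.0
prevalence,delayed_orgasm,2.6
prevalence,breast_swelling_and_tenderness,4.4
prevalence,decreased_sweating,2.1
prevalence,flashing_lights,2.6
severity,blurred_vision,8.2
severity,body_odor,6.4
severity,chills,23.2
severity,concentration,13.4
severity,cracking_at_corners_of_mouth,23.3
severity,dizziness,16.7
severity,heart_palpitations,18.5
severity,hiccups,17.9
severity,memory,11.7
severity,nosebleed,10.5
severity,watery_eyes,10.3
severity,wheezing,19.2
severity,fatigue,39.4
severity,pain_with_sexual_intercourse,43.8
severity,breast_swelling_and_tenderness,39.1
severity,radiation_skin_reaction,31.6
interference,urinary_frequency,23.5
interference,urinary_urgency,16.2
interference,mouth_throat_sores,23.3
interference,fecal_incontinence,21.4
interference,headache,21.0
interference,concentration,17.8
interference,dizziness,16.7
interference,memory,15.2
interference,blurred_vision,7.5
interference,watery_eyes,2.3
frequency,urinary_urgency,23.7
frequency,nosebleed,16.7
frequency,urinary_frequency,43.5
frequency,headache,37.4
frequency,ejaculation,36.4
frequency,chills,31.1
frequency,hiccups,29.4
frequency,heart_palpitations,29.3
frequency,fecal_incontinence,25.0
amount,vaginal_discharge,68.6
amount,hair_loss,16.4
impact,achieve_and_maintain_erection,11.1
impact,bloating,0.0
impact,bruising,11.1
impact,decreased_libido,11.1
impact,discouraged,11.1
impact,gas,0.0
impact,hoarseness,22.2
impact,hot_flashes,22.2
impact,increased_sweating,11.1
impact,nail_ridging,0.0
impact,vaginal_discharge,22.2
impact,vaginal_dryness,11.1
impact,voice_quality_changes,22.2
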