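symptom_id,label
S01,Difficulty concentrating
S02,Pain
S03,Lack of energy
S04,Cough
S05,Nervousness
S06,Dry mouth
S07,Nausea
S08,Drowsiness
S09,Numbness or tingling
S10,Restless sleep
S11,Bloating
S12,Urination problems
S13,Vomiting
S14,Shortness of breath
S15,Diarrhea
S16,Sadness
S17,Excessive sweating
S18,Anxiety
S19,Decreased libido
S20,Itchy skin
S21,Loss of appetite
S22,Dizziness
S23,Difficulty swallowing
S24,Irritability
S25,Mouth ulcers
S26,Change in taste
S27,Weight loss
S28,Hair loss
S29,Constipation
S30,Swelling of legs or arms
S31,I don't look like myself
S32,Skin changes
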