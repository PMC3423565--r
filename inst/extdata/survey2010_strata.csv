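category,hepatitis,treatment,outcome,count,printed
no_coma,TRUE,medical_only,survived,72,TRUE
no_coma,TRUE,medical_only,died,11,TRUE
no_coma,TRUE,transplant,survived,2,FALSE
no_coma,TRUE,transplant,died,0,FALSE
acute,TRUE,medical_only,survived,13,TRUE
acute,TRUE,medical_only,died,28,TRUE
acute,TRUE,transplant,survived,8,FALSE
acute,TRUE,transplant,died,5,FALSE
subacute,TRUE,medical_only,survived,7,TRUE
subacute,TRUE,medical_only,died,29,TRUE
subacute,TRUE,transplant,survived,8,FALSE
subacute,TRUE,transplant,died,5,FALSE
lohf,TRUE,medical_only,survived,0,TRUE
lohf,TRUE,medical_only,died,8,TRUE
lohf,TRUE,transplant,survived,0,FALSE
lohf,TRUE,transplant,died,1,FALSE
no_coma,FALSE,medical_only,survived,5,TRUE
no_coma,FALSE,medical_only,died,6,TRUE
acute,FALSE,medical_only,survived,1,TRUE
acute,FALSE,medical_only,died,6,TRUE
subacute,FALSE,medical_only,survived,0,TRUE
subacute,FALSE,medical_only,died,5,TRUE
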