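misspelling	correction
pateint	patient
depresion	depression
anxeity	anxiety
recieve	receive
occured	occurred
seperate	separate
definately	definitely
apointment	appointment
perscription	prescription
symtoms	symptoms
alchohol	alcohol
suicidel	suicidal
theraphy	therapy
sleeep	sleep
familly	family
excercise	exercise
routiene	routine
freinds	friends
monh	month
hystory	history
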