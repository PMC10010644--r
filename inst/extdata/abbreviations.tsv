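# Starter radiology abbreviation dictionary (token <TAB> expansion).
sob	shortness of breath
cp	chest pain
ap	anteroposterior
pa	posteroanterior
lat	lateral
cxr	chest xray
copd	chronic obstructive pulmonary disease
chf	congestive heart failure
ptx	pneumothorax
effus	effusion
bibasilar	bilateral basilar
cabg	coronary artery bypass graft
ett	endotracheal tube
ngt	nasogastric tube
picc	peripherally inserted central catheter
ivc	inferior vena cava
svc	superior vena cava
dx	diagnosis
hx	history
wnl	within normal limits
nad	no acute disease
rml	right middle lobe
rll	right lower lobe
lll	left lower lobe
rul	right upper lobe
lul	left upper lobe
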