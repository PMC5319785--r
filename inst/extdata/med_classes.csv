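drug_name,med_class
lisinopril,ACEI_ARB
enalapril,ACEI_ARB
captopril,ACEI_ARB
ramipril,ACEI_ARB
benazepril,ACEI_ARB
quinapril,ACEI_ARB
fosinopril,ACEI_ARB
losartan,ACEI_ARB
valsartan,ACEI_ARB
irbesartan,ACEI_ARB
olmesartan,ACEI_ARB
candesartan,ACEI_ARB
telmisartan,ACEI_ARB
metoprolol,BETA_BLOCKER
atenolol,BETA_BLOCKER
carvedilol,BETA_BLOCKER
propranolol,BETA_BLOCKER
bisoprolol,BETA_BLOCKER
nebivolol,BETA_BLOCKER
labetalol,BETA_BLOCKER
nadolol,BETA_BLOCKER
diltiazem,NONDHP_CCB
verapamil,NONDHP_CCB
amlodipine,DHP_CCB
nifedipine,DHP_CCB
felodipine,DHP_CCB
nicardipine,DHP_CCB
isradipine,DHP_CCB
nisoldipine,DHP_CCB
hydralazine,HYDRALAZINE
minoxidil,MINOXIDIL
clonidine,CENTRAL_ALPHA_AGONIST
methyldopa,CENTRAL_ALPHA_AGONIST
guanfacine,CENTRAL_ALPHA_AGONIST
guanabenz,CENTRAL_ALPHA_AGONIST
aliskiren,DIRECT_RENIN_ANTAGONIST
spironolactone,ALDOSTERONE_ANTAGONIST
eplerenone,ALDOSTERONE_ANTAGONIST
doxazosin,ALPHA_ANTAGONIST
prazosin,ALPHA_ANTAGONIST
terazosin,ALPHA_ANTAGONIST
hydrochlorothiazide,THIAZIDE_DIURETIC
chlorthalidone,THIAZIDE_DIURETIC
indapamide,THIAZIDE_DIURETIC
metolazone,THIAZIDE_DIURETIC
chlorothiazide,THIAZIDE_DIURETIC
amiloride,K_SPARING_DIURETIC
triamterene,K_SPARING_DIURETIC
furosemide,LOOP_DIURETIC
bumetanide,LOOP_DIURETIC
torsemide,LOOP_DIURETIC
ethacrynic acid,LOOP_DIURETIC
phentolamine,EXCLUDED
phenoxybenzamine,EXCLUDED
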