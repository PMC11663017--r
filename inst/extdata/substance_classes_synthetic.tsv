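substance	drug_class	is_psychedelic
Cannabis	cannabinoid	FALSE
MDMA	entactogen	FALSE
LSD	lysergamide	TRUE
Salvia divinorum	atypical hallucinogen	FALSE
Mushrooms	tryptamine	TRUE
DMT	tryptamine	TRUE
DXM	dissociative	FALSE
Mushrooms_P. cubensis	tryptamine	TRUE
Cocaine	stimulant	FALSE
Ketamine	dissociative	FALSE
Morning Glory	lysergamide	TRUE
Amphetamines	stimulant	FALSE
Kratom	opioid	FALSE
2C-I	phenethylamine	TRUE
Methamphetamine	stimulant	FALSE
Syrian Rue	herb/nootropic	FALSE
H.B. Woodrose	lysergamide	TRUE
Nitrous Oxide	dissociative	FALSE
2C-B	phenethylamine	TRUE
2C-E	phenethylamine	TRUE
Heroin	opioid	FALSE
Oxycodone	opioid	FALSE
5-MeO-DMT	tryptamine	TRUE
Alcohol	depressant	FALSE
Pharms_Tramadol	opioid	FALSE
Nutmeg	deliriant	FALSE
Pharms_Zolpidem	depressant	FALSE
Diphenhydramine	deliriant	FALSE
Datura	deliriant	FALSE
Amanitas_A. muscaria	deliriant	FALSE
Hydrocodone	opioid	FALSE
Pharms_Alprazolam	depressant	FALSE
Caffeine	stimulant	FALSE
5-MeO-DiPT	tryptamine	TRUE
4-AcO-DMT	tryptamine	TRUE
AMT	stimulant	FALSE
Cacti_T. pachanoi	phenethylamine	TRUE
Alcohol_Beer_Wine	depressant	FALSE
Alcohol_Hard	depressant	FALSE
Pharms_Clonazepam	depressant	FALSE
Kava	depressant	FALSE
Pharms_Buprenorphine	opioid	FALSE
Codeine	opioid	FALSE
2C-T-7	phenethylamine	TRUE
25I-NBOMe	phenethylamine	TRUE
Dimenhydrinate	deliriant	FALSE
Methoxetamine	dissociative	FALSE
Pharms_Methylphenidate	stimulant	FALSE
Mimosa tenuiflora	tryptamine	TRUE
DPT	tryptamine	TRUE
Inhalants	dissociative	FALSE
GHB	depressant	FALSE
Modafinil	stimulant	FALSE
Huasca Combo	tryptamine	TRUE
Products_Spice-Like Smoking Blends	cannabinoid	FALSE
Methylone	entactogen	FALSE
Ayahuasca	tryptamine	TRUE
Pharms_Bupropion	antidepressant	FALSE
Pharms_Gabapentin	depressant	FALSE
2C-T-2	phenethylamine	TRUE
Pharms_Venlafaxine	antidepressant	FALSE
Methadone	opioid	FALSE
Morphine	opioid	FALSE
4-Methylmethcathinone	entactogen	FALSE
Tobacco	stimulant	FALSE
MDA	entactogen	FALSE
Calea zacatechichi	herb/nootropic	FALSE
Poppies_Opium	opioid	FALSE
Banisteriopsis caapi	herb/nootropic	FALSE
Melatonin	depressant	FALSE
Pharms_Paroxetine	antidepressant	FALSE
Crack	stimulant	FALSE
Pharms_Quetiapine	depressant	FALSE
Cannabis_Hash	cannabinoid	FALSE
Lotus_Lily_Nymphaea nouchali var. caerulea	herb/nootropic	FALSE
5-MeO-AMT	tryptamine	TRUE
Pharms_Pregabalin	depressant	FALSE
Absinthe	depressant	FALSE
25C-NBOMe	phenethylamine	TRUE
Smarts_Phenibut	depressant	FALSE
Damiana	herb/nootropic	FALSE
Pharms_Diazepam	depressant	FALSE
1P-LSD	lysergamide	TRUE
PCP	dissociative	FALSE
Catnip	herb/nootropic	FALSE
Valerian	depressant	FALSE
4-HO-MET	tryptamine	TRUE
Cacti_T. peruvianus	phenethylamine	TRUE
Pharms_Fentanyl	opioid	FALSE
2C-C	phenethylamine	TRUE
5-MeO-MIPT	tryptamine	TRUE
MDPV	stimulant	FALSE
Etizolam	depressant	FALSE
Pharms_Lorazepam	depressant	FALSE
JWH-018	cannabinoid	FALSE
Sceletium tortuosum	herb/nootropic	FALSE
Wormwood	herb/nootropic	FALSE
DOC	phenethylamine	TRUE
Pharms_Sertraline	antidepressant	FALSE
Mescaline	phenethylamine	TRUE
Brugmansia	deliriant	FALSE
Piracetam	herb/nootropic	FALSE
Huasca Brew	tryptamine	TRUE
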