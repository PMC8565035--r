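source_vocabulary	source_code	target_concept_id	priority	provenance
MedDRA	10057688	4249456	1	manual
MedDRA	10057688	4183956	2	manual
MedDRA	10038435	4030518	1	automated
MedDRA	10020772	4000050	1	automated
MedDRA	10003658	4000051	1	automated
MedDRA	10013968	4000052	1	automated
MedDRA	10012727	4000053	1	automated
WHODrug	000001	4000101	1	manual
WHODrug	000002	4000102	1	manual
WHODrug	000003	4000103	1	manual
free-text	drug- and toxin-induced pah	2000000001	1	custom
free-text	ph with unclear or multifactorial mechanisms	2000000002	1	custom
free-text	pah associated with connective tissue disease	4000010	1	custom
free-text	pah associated with connective tissue disease	4000030	2	custom
free-text	pah associated with congenital heart disease	4000010	1	custom
free-text	pah associated with congenital heart disease	4000040	2	custom
free-text	pulmonary hypertension	4322024	1	manual
free-text	hospitalization	9201	1	manual
free-text	macitentan tablets	4000101	1	manual
free-text	investigational prostacyclin analogue	2000000005	1	custom
free-text	mild	4000311	1	manual
free-text	moderate	4285732	1	manual
free-text	severe	4000313	1	manual
free-text	yes	45877994	1	manual
free-text	no	45878245	1	manual
free-text	possible	4162850	1	manual
free-text	unlikely	45877241	1	manual
free-text	recovered	4000301	1	manual
free-text	not recovered	4000302	1	manual
free-text	other reason	45885208	1	manual
free-text	thermodilution	4122989	1	manual
SDTM-TEST	NTPROBNP	3029435	1	manual
SDTM-TEST	CREAT	3016723	1	manual
SDTM-TEST	SYSBP	3004249	1	manual
SDTM-TEST	MPAP	3028074	1	manual
SDTM-TEST	WHOFC	2000000010	1	manual
VAL-WHOFC	I	2000000011	1	manual
VAL-WHOFC	II	2000000012	1	manual
VAL-WHOFC	III	2000000013	1	manual
VAL-WHOFC	IV	2000000014	1	manual
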