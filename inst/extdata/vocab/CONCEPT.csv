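concept_id	concept_name	domain_id	vocabulary_id	concept_class_id	standard_concept	concept_code	valid_start_date	valid_end_date	invalid_reason
4030518	Renal impairment	Condition	SNOMED	Clinical Finding	S	236423003	1970-01-01	2099-12-31
4022772	Condition severity	Observation	SNOMED	Observable Entity	S	246112005	1970-01-01	2099-12-31
4285732	Moderate	Meas Value	SNOMED	Qualifier Value	S	6736007	1970-01-01	2099-12-31
3028074	Pulmonary artery Mean blood pressure	Measurement	LOINC	Clinical Observation	S	8414-8	1970-01-01	2099-12-31
4122989	Thermodilution technique	Observation	SNOMED	Procedure	S	129118005	1970-01-01	2099-12-31
4152892	Measurement method	Metadata	SNOMED	Attribute	S	370129005	1970-01-01	2099-12-31
1147304	observation	Metadata	CDM	CDM Table	S	CDM.observation	1970-01-01	2099-12-31
1147330	measurement	Metadata	CDM	CDM Table	S	CDM.measurement	1970-01-01	2099-12-31
1147333	condition_occurrence	Metadata	CDM	CDM Table	S	CDM.condition_occurrence	1970-01-01	2099-12-31
1147339	drug_exposure	Metadata	CDM	CDM Table	S	CDM.drug_exposure	1970-01-01	2099-12-31
1147301	procedure_occurrence	Metadata	CDM	CDM Table	S	CDM.procedure_occurrence	1970-01-01	2099-12-31
1147332	visit_occurrence	Metadata	CDM	CDM Table	S	CDM.visit_occurrence	1970-01-01	2099-12-31
1147900	Event characteristic link	Metadata	CDM	CDM Attribute	S	CDM.characteristic_link	1970-01-01	2099-12-31
1147901	Concept combination link	Metadata	CDM	CDM Attribute	S	CDM.combination_link	1970-01-01	2099-12-31
44807982	Participant in research study	Observation	SNOMED	Clinical Finding	S	428024001	1970-01-01	2099-12-31
4090379	Patient entered into trial	Observation	SNOMED	Clinical Finding	S	185320005	1970-01-01	2099-12-31
44811375	Consent given to participate in research study	Observation	SNOMED	Clinical Finding	S	427778005	1970-01-01	2099-12-31
4163733	Patient consented to clinical trial	Observation	SNOMED	Clinical Finding	S	275508000	1970-01-01	2099-12-31
44810922	Participation in research study completed	Observation	SNOMED	Clinical Finding	S	428482006	1970-01-01	2099-12-31
44810920	Withdrawn from research study	Observation	SNOMED	Clinical Finding	S	428478009	1970-01-01	2099-12-31
40482840	Completion of clinical trial	Observation	SNOMED	Clinical Finding	S	446849009	1970-01-01	2099-12-31
4087907	Patient withdrawn from trial	Observation	SNOMED	Clinical Finding	S	184049006	1970-01-01	2099-12-31
4249456	Complication of catheter	Condition	SNOMED	Clinical Finding	S	79757003	1970-01-01	2099-12-31
4183956	Skin discharge	Condition	SNOMED	Clinical Finding	S	271761007	1970-01-01	2099-12-31
4231813	Adverse incident outcome categories	Observation	SNOMED	Observable Entity	S	278986008	1970-01-01	2099-12-31
45878245	No	Meas Value	SNOMED	Qualifier Value	S	373067005	1970-01-01	2099-12-31
45877241	Unlikely	Meas Value	SNOMED	Qualifier Value	S	1491118017	1970-01-01	2099-12-31
45877994	Yes	Meas Value	SNOMED	Qualifier Value	S	373066001	1970-01-01	2099-12-31
4162850	Possible	Meas Value	SNOMED	Qualifier Value	S	60022001	1970-01-01	2099-12-31
45885208	Other reason	Meas Value	SNOMED	Qualifier Value	S	74964007	1970-01-01	2099-12-31
4322024	Pulmonary hypertension	Condition	SNOMED	Clinical Finding	S	70995007	1970-01-01	2099-12-31
4000010	Pulmonary arterial hypertension	Condition	SNOMED	Clinical Finding	S	11399002	1970-01-01	2099-12-31
4000020	Chronic thromboembolic pulmonary hypertension	Condition	SNOMED	Clinical Finding	S	233947005	1970-01-01	2099-12-31
4000030	Connective tissue disease overlap syndrome	Condition	SNOMED	Clinical Finding	S	239989006	1970-01-01	2099-12-31
4000040	History of surgically corrected congenital heart defect	Condition	SNOMED	Clinical Finding	S	429559004	1970-01-01	2099-12-31
4000050	Hypertensive disorder	Condition	SNOMED	Clinical Finding	S	38341003	1970-01-01	2099-12-31
4000051	Atrial fibrillation	Condition	SNOMED	Clinical Finding	S	49436004	1970-01-01	2099-12-31
4000052	Dyspnea	Condition	SNOMED	Clinical Finding	S	267036007	1970-01-01	2099-12-31
4000053	Diabetes mellitus	Condition	SNOMED	Clinical Finding	S	73211009	1970-01-01	2099-12-31
4000101	macitentan	Drug	RxNorm	Ingredient	S	1442132	1970-01-01	2099-12-31
4000102	selexipag	Drug	RxNorm	Ingredient	S	1747005	1970-01-01	2099-12-31
4000103	sildenafil	Drug	RxNorm	Ingredient	S	136411	1970-01-01	2099-12-31
3029435	NT-proBNP serum level	Measurement	LOINC	Lab Test	S	33762-6	1970-01-01	2099-12-31
3016723	Creatinine serum level	Measurement	LOINC	Lab Test	S	2160-0	1970-01-01	2099-12-31
3004249	Systolic blood pressure	Measurement	LOINC	Clinical Observation	S	8480-6	1970-01-01	2099-12-31
9201	Inpatient Visit	Visit	Visit	Visit	S	IP	1970-01-01	2099-12-31
4000311	Mild	Meas Value	SNOMED	Qualifier Value	S	255604002	1970-01-01	2099-12-31
4000313	Severe	Meas Value	SNOMED	Qualifier Value	S	24484000	1970-01-01	2099-12-31
4000301	Recovered/resolved	Meas Value	SNOMED	Qualifier Value	S	723506003	1970-01-01	2099-12-31
4000302	Not recovered	Meas Value	SNOMED	Qualifier Value	S	723505004	1970-01-01	2099-12-31
8507	MALE	Gender	Gender	Gender	S	M	1970-01-01	2099-12-31
8532	FEMALE	Gender	Gender	Gender	S	F	1970-01-01	2099-12-31
35000001	Catheter site discharge	Condition	MedDRA	PT	C	10057688	1970-01-01	2099-12-31
35000002	Renal impairment	Condition	MedDRA	PT	C	10038435	1970-01-01	2099-12-31
35000003	Hypertension	Condition	MedDRA	PT	C	10020772	1970-01-01	2099-12-31
35000004	Atrial fibrillation	Condition	MedDRA	PT	C	10003658	1970-01-01	2099-12-31
35000005	Dyspnoea	Condition	MedDRA	PT	C	10013968	1970-01-01	2099-12-31
35000006	Diabetes mellitus	Condition	MedDRA	PT	C	10012727	1970-01-01	2099-12-31
2000000001	Drug- and toxin-induced PAH	Condition	Custom	Custom	S	drug- and toxin-induced pah	1970-01-01	2099-12-31
2000000002	PH with unclear or multifactorial mechanisms	Condition	Custom	Custom	S	ph with unclear or multifactorial mechanisms	1970-01-01	2099-12-31
2000000005	Investigational prostacyclin analogue	Drug	Custom	Custom	S	investigational prostacyclin analogue	1970-01-01	2099-12-31
2000000010	WHO functional class	Observation	Custom	Custom	S	who functional class	1970-01-01	2099-12-31
2000000011	WHO functional class I	Meas Value	Custom	Custom	S	who functional class i	1970-01-01	2099-12-31
2000000012	WHO functional class II	Meas Value	Custom	Custom	S	who functional class ii	1970-01-01	2099-12-31
2000000013	WHO functional class III	Meas Value	Custom	Custom	S	who functional class iii	1970-01-01	2099-12-31
2000000014	WHO functional class IV	Meas Value	Custom	Custom	S	who functional class iv	1970-01-01	2099-12-31
2000000020	Relationship to study drug	Observation	Custom	Custom	S	relationship to study drug	1970-01-01	2099-12-31
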