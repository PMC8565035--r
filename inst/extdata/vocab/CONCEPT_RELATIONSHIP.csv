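concept_id_1	concept_id_2	relationship_id	valid_start_date	valid_end_date	invalid_reason
35000001	4249456	Maps to	1970-01-01	2099-12-31
35000001	4183956	Maps to	1970-01-01	2099-12-31
35000002	4030518	Maps to	1970-01-01	2099-12-31
35000003	4000050	Maps to	1970-01-01	2099-12-31
35000004	4000051	Maps to	1970-01-01	2099-12-31
35000005	4000052	Maps to	1970-01-01	2099-12-31
35000006	4000053	Maps to	1970-01-01	2099-12-31
4000010	4322024	Is a	1970-01-01	2099-12-31
4000020	4322024	Is a	1970-01-01	2099-12-31
2000000001	4000010	Is a	1970-01-01	2099-12-31
2000000002	4322024	Is a	1970-01-01	2099-12-31
2000000011	2000000010	Is a	1970-01-01	2099-12-31
2000000012	2000000010	Is a	1970-01-01	2099-12-31
2000000013	2000000010	Is a	1970-01-01	2099-12-31
2000000014	2000000010	Is a	1970-01-01	2099-12-31
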