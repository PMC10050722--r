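{"AD001|1":{"group":"AD","task_score":1,"moca_bc":12,"mmse":24,"demographics":{"gender":"male","age":76,"education_years":14,"work_nature":"physical","residence_status":"with_spouse","residence_area":"rural","income_band":">=5000"}},"HC001|1":{"group":"HC","task_score":1,"moca_bc":28,"mmse":28,"demographics":{"gender":"female","age":69,"education_years":10,"work_nature":"physical","residence_status":"with_spouse","residence_area":"rural","income_band":">=5000"}}}
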