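# session_id=fixture-5trial
# task_kind=multispout
# config_digest=00000000
# seed=0
# schema_version=1
# access_ms=3000
# n_trials=5
# solution_by_trial=0,1,2,3,4
# spout_by_trial=0,1,2,3,4
time_ms,code,value
0,session_start,0
0,trial_start,0
0,spout_extend_cmd,0
3000,spout_retract_cmd,0
3000,trial_end,0
8000,trial_start,1
8000,spout_extend_cmd,1
8250,lick,1
8250,solenoid_open,1
8400,lick,1
8400,solenoid_open,1
8550,lick,1
8550,solenoid_open,1
11000,spout_retract_cmd,1
11000,trial_end,1
17000,trial_start,2
17000,spout_extend_cmd,2
17100,lick,2
17100,solenoid_open,2
19900,lick,2
19900,solenoid_open,2
20000,spout_retract_cmd,2
20000,trial_end,2
26000,trial_start,3
26000,spout_extend_cmd,3
26500,lick,3
26500,solenoid_open,3
26650,lick,3
26650,solenoid_open,3
26800,lick,3
26800,solenoid_open,3
26950,lick,3
26950,solenoid_open,3
27100,lick,3
27100,solenoid_open,3
29000,spout_retract_cmd,3
29000,trial_end,3
35000,trial_start,4
35000,spout_extend_cmd,4
35010,lick,4
35010,solenoid_open,4
38000,spout_retract_cmd,4
38000,trial_end,4
38000,session_end,0
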