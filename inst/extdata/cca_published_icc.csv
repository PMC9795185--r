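task_id,interval,n_pairs,icc
jumping_jacks,0-12,52,0.56
pylon_obstacle,0-12,50,0.38
backwards_tandem,0-12,17,0.83
shuttle_run,0-12,39,0.48
ins_and_outs,0-12,39,0.73
long_jump,0-12,50,0.81
jumping_jacks,12-24,14,0.24
pylon_obstacle,12-24,14,-0.34
backwards_tandem,12-24,7,0.63
shuttle_run,12-24,14,0.46
ins_and_outs,12-24,8,-0.40
long_jump,12-24,14,0.56
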