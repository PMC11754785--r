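comparison	n_significant	total
var2_WL-abc1k1_WL	5	9086
var2_WL-Col_WL	2	9086
abc1k1_WL-Col_WL	1	9086
var2_RL-var2_WL	4363	9086
abc1k1_RL-abc1k1_WL	2936	9086
Col_RL-Col_WL	1200	9086
var2_RL-Col_RL	974	9086
abc1k1_RL-Col_RL	965	9086
var2_RL-abc1k1_RL	222	9086
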