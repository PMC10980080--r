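quantity	count
n_total	18098
n_same	11075
n_younger_by_synteny	6707
n_younger_by_similarity	316
n_early_by_synteny	10867
n_early_by_similarity	17154
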