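metric,value
adir_prospective_total,626
cdir_prospective_total,696
both_detected,528
adir_only,98
cdir_only,168
adir_retrospective_total,679
cdir_retrospective_total,722
adir_retrospective_increment,53
cdir_retrospective_increment,26
cdir_only_recovered_retrospectively,53
adir_only_recovered_retrospectively,30
n_subjects,15
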