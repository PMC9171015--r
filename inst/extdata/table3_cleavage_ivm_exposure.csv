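group,category,count
control,uncleaved,58
control,le8cell,103
control,gt8cell,116
vehicle,uncleaved,64
vehicle,le8cell,114
vehicle,gt8cell,104
1e-9 M,uncleaved,82
1e-9 M,le8cell,85
1e-9 M,gt8cell,116
1e-7 M,uncleaved,74
1e-7 M,le8cell,104
1e-7 M,gt8cell,103
1e-5 M,uncleaved,88
1e-5 M,le8cell,114
1e-5 M,gt8cell,73
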