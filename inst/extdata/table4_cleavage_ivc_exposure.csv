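group,category,count
control,uncleaved,47
control,le8cell,106
control,gt8cell,87
vehicle,uncleaved,45
vehicle,le8cell,99
vehicle,gt8cell,95
1e-9 M,uncleaved,43
1e-9 M,le8cell,97
1e-9 M,gt8cell,100
1e-7 M,uncleaved,50
1e-7 M,le8cell,86
1e-7 M,gt8cell,104
1e-5 M,uncleaved,31
1e-5 M,le8cell,102
1e-5 M,gt8cell,97
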