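"viewer","receptor","lambda_max","density"
"hawkmoth","UV",357,0.1
"hawkmoth","B",450,0.23
"hawkmoth","G",520,0.67
"blowfly","R7p",330,1
"blowfly","R8p",460,1
"blowfly","R7y",350,1
"blowfly","R8y",530,1
"hoverfly","R7p",330,1
"hoverfly","R8p",460,1
"hoverfly","R7y",350,1
"hoverfly","R8y",530,1
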