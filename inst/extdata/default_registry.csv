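"stratum","family","par1","par2","cap_years"
"HCC","loglogistic",1.66290034832616,1555.72933201647,10
"PBC","loglogistic",1.66290034832616,5126.83529869062,10
"PSC","loglogistic",1.66290034832616,6321.91828555782,10
"ALF","loglogistic",1.66290034832616,1576.9438229076,10
"AC","loglogistic",1.66290034832616,3839.82285129518,10
"Others","loglogistic",1.66290034832616,3571.10596667416,10
"palliative","loglogistic",2.58316761258386,659.441355082324,10
"SECA1","loglogistic",1.77011646269683,1793.64481742519,10
"SECA2","loglogistic",2.10479098462748,3114.75705737296,10
"wl_death:HCC","exponential",4281.94607268464,NA,NA
"wl_death:PBC","exponential",4281.94607268464,NA,NA
"wl_death:PSC","exponential",4281.94607268464,NA,NA
"wl_death:ALF","exponential",4281.94607268464,NA,NA
"wl_death:AC","exponential",4281.94607268464,NA,NA
"wl_death:Others","exponential",4281.94607268464,NA,NA
"wl_death:CRLM","exponential",4281.94607268464,NA,NA
"wl_dropout:HCC","exponential",4281.94607268464,NA,NA
"wl_dropout:PBC","exponential",4281.94607268464,NA,NA
"wl_dropout:PSC","exponential",4281.94607268464,NA,NA
"wl_dropout:ALF","exponential",4281.94607268464,NA,NA
"wl_dropout:AC","exponential",4281.94607268464,NA,NA
"wl_dropout:Others","exponential",4281.94607268464,NA,NA
"wl_dropout:CRLM","exponential",4281.94607268464,NA,NA
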