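serum,endpoint_titer,drug,ic50_uM,censored
6-AcMorHap,819200,heroin,0.5,FALSE
6-AcMorHap,819200,6-AM,1.1,FALSE
6-AcMorHap,819200,morphine,0.1,FALSE
6-PrOxyHap,409600,heroin,2.2,FALSE
6-PrOxyHap,409600,6-AM,7.5,FALSE
6-PrOxyHap,409600,morphine,1.6,FALSE
MorHap,1638400,heroin,NA,TRUE
MorHap,1638400,6-AM,21.4,FALSE
MorHap,1638400,morphine,9.182,FALSE
DiAmHap,204800,heroin,NA,TRUE
DiAmHap,204800,6-AM,NA,TRUE
DiAmHap,204800,morphine,NA,TRUE
DiPrOxyHap,102400,heroin,16.8,FALSE
DiPrOxyHap,102400,6-AM,144.9,FALSE
DiPrOxyHap,102400,morphine,NA,TRUE
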