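label,sex,pregnant,age_min,age_max,ear_mg,ul_mg
children 0.5 to <1,any,FALSE,0.5,1,270,1500
children 1 to <4,any,FALSE,1,4,400,2500
children 4 to <9,any,FALSE,4,9,640,2500
females 9 to <14,female,FALSE,9,14,1100,3000
females 14 to <19,female,FALSE,14,19,1100,3000
females 19 to <31,female,FALSE,19,31,800,2500
females 31 to <51,female,FALSE,31,51,800,2500
females 51 to <71,female,FALSE,51,71,1000,2000
females 71+,female,FALSE,71,Inf,1000,2000
males 9 to <14,male,FALSE,9,14,1100,3000
males 14 to <19,male,FALSE,14,19,1100,3000
males 19 to <31,male,FALSE,19,31,800,2500
males 31 to <51,male,FALSE,31,51,800,2500
males 51 to <71,male,FALSE,51,71,800,2000
males 71+,male,FALSE,71,Inf,1000,2000
pregnant 14 to <19,female,TRUE,14,19,1100,3000
pregnant 19 to <31,female,TRUE,19,31,800,2500
pregnant 31 to <51,female,TRUE,31,51,800,2500
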