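region,Intercept,Month,Indicator_Heroin,MonthsSince_Heroin,Indicator_Fentanyl,MonthsSince_Fentanyl,MonthsSince_PHE,Indicator_COVID,MonthsSince_COVID,MonthsSince_CHW
Northeast,0.2729,0.0018,-0.0509,0.0045,-0.1043,0.0150,-0.0153,0.3701,-0.0006,0.0014
Midwest,0.1069,0.0033,0.0173,0.0000,-0.0771,0.0122,-0.0177,0.5409,0.0070,-0.0029
South,0.1920,0.0032,-0.01112,-0.0036,-0.0713,0.0110,-0.0082,0.5231,0.0178,-0.0160
West,0.2972,0.0026,-0.0263,-0.0031,0.0155,0.0014,0.0076,0.3132,0.0210,-0.0246
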