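construct,filter_code,ammonia_rate,ammonia_se,water_rate,water_se,is_background
Empty vector,,6.7,0.1,0.25,0.01,TRUE
AtTIP2;1,HHIGR,39.1,0.1,10.5,0.1,FALSE
HsAQP1 wt,FNHCR,6.3,0.04,33.5,0.2,FALSE
N127H (LCP),FHHCR,4.7,0.03,1.4,0.001,FALSE
F56H (H2P) N127H (LCP),HHHCR,6.1,0.04,1.9,0.01,FALSE
H180I (H5P),FNICR,11.5,0.1,0.57,0.0005,FALSE
N127H (LCP) H180I (H5P),FHICR,5.5,0.03,0.31,0.0004,FALSE
F56H (H2P) N127H (LCP) H180I (H5P),HHICR,9.9,0.1,0.33,0.0005,FALSE
F56H (H2P) N127H (LCP) H180I (H5P) C189G (LEP),HHIGR,12.4,0.1,2.2,0.02,FALSE
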