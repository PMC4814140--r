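construct,host,code,complementation,in_vivo_exception
AtTIP2;1 wt,AtTIP2;1,HHIGR,+,FALSE
H63F (H2P),AtTIP2;1,FHIGR,-,FALSE
H131F (LCP),AtTIP2;1,HFIGR,+,FALSE
I185H (H5P),AtTIP2;1,HHHGR,+,FALSE
G194C (LEP),AtTIP2;1,HHICR,+,FALSE
I185H (H5P) G194C (LEP),AtTIP2;1,HHHCR,-,FALSE
AtTIP2;1 quadruple,AtTIP2;1,FNHCR,-,FALSE
HsAQP1 wt,HsAQP1,FNHCR,-,FALSE
N127H (LCP),HsAQP1,FHHCR,-,FALSE
F56H (H2P) N127H (LCP),HsAQP1,HHHCR,-,FALSE
H180I (H5P),HsAQP1,FNICR,-,TRUE
N127H (LCP) H180I (H5P),HsAQP1,FHICR,-,TRUE
F56H (H2P) N127H (LCP) H180I (H5P),HsAQP1,HHICR,-,TRUE
HsAQP1 quadruple,HsAQP1,HHIGR,+,FALSE
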