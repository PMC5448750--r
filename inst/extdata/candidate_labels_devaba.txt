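# Candidate connectivity labels from the developmental-atlas expression screen
# (one gene symbol per line)
Alcam
Astn2
Bmp3
Cadm1
Cbln2
Cbln4
Cd47
Cdh2
Cdh4
Cdh6
Cdh7
Cdh8
Cdh9
Cdh10
Cdh11
Cdh12
Cdh13
Cdh24
Clstn1
Clstn2
Cntn6
Cntnap4
Dlk1
Dner
EfnA2
EfnA5
EfnB3
EphA1
EphA3
EphA4
EphA6
EphA8
EphA10
EphB1
EphB2
EphB6
Fat3
Flt3
Fzd7
Gfra1
Gfra2
Gpc3
Igfbp5
Inhba
Kit
Lgi2
Lrp8
Lrrn3
Lypd1
Mdga1
Nrn
Ntng1
Ntng2
Ntrk2
Ntrk3
Pcdh1
Pcdh10
Pcdh11X
Pcdh19
Pcdh21
PlxnA1
PlxnA2
PlxnC1
Ptpru
Ret
Rtn4rl1
Sema3F
Sema6A
Sema7A
Odz3
Tgfb2
Trp53i11
Vgf
Wif1
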