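# Candidate connectivity labels from the conserved-orthology screen
# (one gene symbol per line)
Clstn1
Clstn2
Igsf9b
Kirrel3
Neto1
Neto2
Odz1
Odz2
Odz3
Odz4
Sdk2
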