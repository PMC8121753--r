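name,polarity,shift_da,charge
[M+H],positive,1.00727646688,1
[M+Na],positive,22.98922070,1
[M+K],positive,38.96315791,1
[M+NH4],positive,18.03382555,1
[M+HCOOH+H],positive,47.01275577,1
[M-H],negative,-1.00727646688,-1
[M+HCOOH-H],negative,44.99820284,-1
[M+Cl],negative,34.96940126,-1
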