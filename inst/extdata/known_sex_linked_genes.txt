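# Curated sex-chromosome genes previously described as sex-biased:
# Xist, Jpx (alias 2010000I03Rik), coding X-inactivation escapees and
# their Y-linked paralogues. Edit freely; one symbol per line.
Xist
Jpx
2010000I03Rik
Kdm5c
Eif2s3x
Kdm6a
Ddx3x
Kdm5d
Eif2s3y
Uty
Ddx3y
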