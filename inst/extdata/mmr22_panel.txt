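# Default 22-gene extended mismatch-repair panel.
# Editable resource: one gene symbol per line; '#' lines are comments.
MLH1
MLH3
MSH2
MSH3
MSH6
PMS1
PMS2
EXO1
POLD1
POLD2
POLD3
POLD4
POLE
PCNA
LIG1
RFC1
RFC2
RFC3
RFC4
RFC5
RPA1
RPA2
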