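# Suggested restriction enzymes: common unambiguous 6-cutters.
# Format: Name RECOG^NITION  (caret = top-strand cut position).
# Order is preference order for linearization, subcloning and tag-flanking
# site selection; customize freely.
EcoRI   G^AATTC
BamHI   G^GATCC
HindIII A^AGCTT
XhoI    C^TCGAG
SalI    G^TCGAC
SacI    GAGCT^C
KpnI    GGTAC^C
NheI    G^CTAGC
SpeI    A^CTAGT
BglII   A^GATCT
MluI    A^CGCGT
AvrII   C^CTAGG
NcoI    C^CATGG
PstI    CTGCA^G
SphI    GCATG^C
XbaI    T^CTAGA
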