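cluster,channel
C1,C2
C1,C4
C1,C6
C1,CP2
C1,CP4
C1,CP6
C2,P2
C2,P4
C2,P6
C2,P8
C4,PO4
C4,PO8
C4,TP8
C4,TP10
C5,O2
C5,Oz
C5,POz
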