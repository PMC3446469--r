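LY6E
HERC5
IFI44L
ISG15
MxA
MxB
EPSTI1
RSAD2
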