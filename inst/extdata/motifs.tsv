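name	pattern
E_box_generic	CANNTG
E_box_canonical	CACGTG
W_box	TTGACY
CRE	TGACGTCA
PERR	CACGCAC
TER	CACGTT
PDP1	TTATGTAA
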