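# Synthetic cutoff-motif library (matches the package's synthetic subfamily
# consensus sequences; NOT a biological cutoff library -- supply your own
# TSV of the same shape for real annotations).
# subfamily	motif
SINEA1	GGAGTTCGGT
SINEA2	GGAGTTCGGT
SINEA3	GGAGTTCGGT
SINEB1	CCTAGGTTCA
SINEB2	CCTAGGTTCA
SINEC1	TGGCGCAATC
*	GGAGTTCGGT
*	CCTAGGTTCA
*	TGGCGCAATC
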