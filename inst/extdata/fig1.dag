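# canonical two-confounder diagram: exposure E, outcome D,
# confounders A and B
A -> E
A -> B
B -> D
E -> D
exposure: E
outcome: D
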