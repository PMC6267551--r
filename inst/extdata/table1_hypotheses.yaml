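# Hypothetical J = 4, R = 7 worked examples: a full ordering and an
# averages hypothesis on the condition success probabilities.
conditions: [c1, c2, c3, c4]
replications: 7
hypotheses:
  H1: "c1 > c2 > c3 > c4"
  H2: "(c1 + c2)/2 > (c3 + c4)/2"
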