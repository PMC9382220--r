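Participants in the treatment condition outperformed controls,
t(178) = 1.90, p = .06, and the interaction of condition with age was
reliable, F(1, 38) = 4.00, p < .05. Response accuracy correlated with
study time, r(48) = .50, p = .0002. Choice frequencies departed from
chance, chi2(2, N = 170) = 14.14, p < .001, and the follow-up contrast
was significant, z = 2.03, p = .04, one-tailed. A final control
comparison was not reliable, t(44) = 1.20, ns.
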