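dishevelled
scruffy
unkempt
groomed
appearance
tidy
presentable
thin
malnourished
hygiene
clothing
dressed
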