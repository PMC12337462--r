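aggressive
agitated
anxious
bad
concern
confused
decline
deteriorate
difficult
dirty
distressed
frail
isolated
lonely
negative
poor
risk
rude
sad
scruffy
unable
unhappy
unsafe
unwell
unwise
worried
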