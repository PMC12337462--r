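dementia
memory
anxious
anxiety
agitated
agitation
depression
depressed
confusion
confused
emotional
mood
distress
distressed
capacity
unwise
disorientated
paranoid
hallucination
wandering
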