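able
active
calm
capable
cheerful
clean
comfortable
content
enjoy
friendly
good
happy
healthy
independent
kind
pleasant
positive
safe
settled
stable
supportive
warm
well
welcoming
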