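mobility
mobilise
fall
pain
incontinence
continence
frail
frailty
ulcer
wound
blister
sight
hearing
breathless
fracture
infection
catheter
medication
swallowing
balance
walking
transfer
pressure
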