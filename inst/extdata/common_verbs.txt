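attend
be
come
cope
cry
do
dress
drink
eat
fall
feel
get
go
have
help
leave
live
make
manage
meet
move
rest
return
see
shout
sit
sleep
smile
speak
stand
stay
struggle
take
talk
try
visit
walk
wander
wash
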