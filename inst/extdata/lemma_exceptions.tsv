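token	lemma
women	woman
men	man
children	child
people	people
fell	fall
fallen	fall
feet	foot
teeth	tooth
went	go
gone	go
said	say
made	make
took	take
taken	take
gave	give
given	give
found	find
kept	keep
felt	feel
told	tell
saw	see
seen	see
got	get
came	come
knew	know
known	know
left	leave
lost	lose
paid	pay
brought	bring
thought	think
stood	stand
sat	sit
ran	run
met	meet
slept	sleep
ate	eat
wrote	write
chose	choose
needs	need
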