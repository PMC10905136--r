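said	say
says	say
saying	say
went	go
goes	go
going	go
gone	go
got	get
gotten	get
gets	get
getting	get
thought	think
thinks	think
thinking	think
made	make
makes	make
making	make
took	take
takes	take
taking	take
taken	take
came	come
comes	come
coming	come
saw	see
seen	see
sees	see
seeing	see
knew	know
known	know
knows	know
knowing	know
felt	feel
feels	feel
feeling	feel
found	find
finds	find
finding	find
gave	give
given	give
gives	give
giving	give
told	tell
tells	tell
telling	tell
ran	run
runs	run
running	run
wrote	write
written	write
writes	write
writing	write
spoke	speak
spoken	speak
speaks	speak
speaking	speak
meant	mean
means	mean
kept	keep
keeps	keep
left	leave
leaves	leave
began	begin
begun	begin
begins	begin
brought	bring
brings	bring
bought	buy
buys	buy
caught	catch
catches	catch
taught	teach
teaches	teach
heard	hear
hears	hear
hearing	hear
held	hold
holds	hold
stood	stand
stands	stand
understood	understand
understands	understand
lost	lose
loses	lose
met	meet
meets	meet
paid	pay
pays	pay
sat	sit
sits	sit
sitting	sit
reads	read
reading	read
liked	like
likes	like
loved	love
loves	love
wanted	want
wants	want
used	use
uses	use
using	use
tried	try
tries	try
trying	try
asked	ask
asks	ask
talked	talk
talks	talk
talking	talk
looked	look
looks	look
looking	look
seemed	seem
seems	seem
happened	happen
happens	happen
children	child
men	man
women	woman
feet	foot
teeth	tooth
mice	mouse
lives	life
wives	wife
knives	knife
selves	self
stories	story
people	people
yes	yes
perhaps	perhaps
always	always
whereas	whereas
alas	alas
besides	besides
sometimes	sometimes
towards	towards
news	news
series	series
species	species
anxious	anxious
previous	previous
obvious	obvious
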