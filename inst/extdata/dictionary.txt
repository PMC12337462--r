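ability
able
about
accept
accepted
accepting
access
ache
active
acute
additionally
administer
administered
adult
advocate
age
agency
aggressive
agitat
agitated
agitation
ago
agree
agreed
agreeing
alarm
alert
alone
also
alzheimer
ambulance
amount
an
anaemia
and
aneurysm
angina
anxiety
anxious
aphasia
appear
appearance
appeared
appears
appetite
appointment
are
arm
arrangement
arrive
arrived
arthritis
as
ask
asked
assess
assessed
assessment
assistance
asthma
at
awake
back
bad
balance
bath
be
became
become
becomes
bed
bedroom
been
before
began
begin
behalf
benefit
bird
birds
blister
blood
breakfast
breath
breathless
bring
british
bronchitis
brother
brought
call
called
calm
can
cancer
cannot
capable
capacity
care
carer
carers
case
cat
cataract
catheter
cellulitis
chair
challeng
challenging
change
changed
charm
charming
cheerful
chest
choice
choices
chronic
circumstance
cirrhosis
city
clean
cleaning
client
close
closed
cloth
clothe
clothes
clothing
coat
comfortable
complex
concern
concerns
conclude
condition
conditions
confus
confused
confusion
consent
constant
constipation
content
continence
continue
continued
cook
cooking
copd
cope
coped
coping
cover
cream
crossword
current
currently
daily
daughter
day
debit
decision
decisions
decline
declined
declining
delirium
deliver
delivered
demand
demanding
dementia
depress
depressed
depression
deputyship
describe
described
despite
deteriorate
deteriorated
deteriorating
diabete
diabetes
diagno
diagnos
diagnosed
diagnosis
difficult
dinner
direct
dirty
disable
disabled
discuss
discussed
disease
dishevell
dishevelled
disorientat
disorientated
distress
distressed
district
doctor
document
documented
dog
doing
dose
dress
dressed
dressing
drink
dur
during
dysphagia
each
early
eat
eating
eczema
elderly
embolism
emergency
emotional
emphasize
emphysema
enjoy
enjoyed
enjoys
environment
environmental
epilepsy
episode
episodes
even
evening
excessive
exist
existed
experienc
experienced
explain
explained
express
expressed
fall
falling
falls
family
fatigue
feel
feet
fell
felt
few
fibromyalgia
find
flat
floor
fluctuate
fluctuated
fluctuates
food
foot
for
forget
forgot
found
fracture
frail
frailty
frame
frequent
fridge
friend
friendly
garden
gardening
give
given
glass
glasses
glaucoma
glove
good
gout
gradual
groom
groomed
ground
hallucination
hand
happy
has
hat
have
he
health
healthy
hear
hearing
heart
heavy
heel
help
hemiplegia
hepatitis
her
highlight
highlighted
hip
history
hoist
home
hospital
hostile
hour
hous
housing
husband
hygiene
hypertension
hyperthyroidism
hypothyroidism
illness
improve
improved
improving
in
include
incontinence
increa
increas
increasing
independent
independently
individual
infection
insomnia
instal
installed
is
isolat
isolated
issue
jone
jones
keep
kept
key
kind
kitchen
knee
know
known
lady
land
last
late
laundry
leave
left
leg
level
like
likes
listen
listening
live
lived
lives
local
lock
locked
lonely
look
looked
lounge
lovely
low
lunch
lymphoedema
make
malnourish
malnourished
manage
managed
managing
many
matter
meal
meals
medication
melanoma
memory
mental
mention
mentioned
mild
minute
mobile
mobilise
mobility
moderate
money
monitor
month
mood
morn
morning
most
move
moved
mrs
near
need
needs
negative
neighbour
neighbours
nephropathy
neuropathy
next
night
noise
note
noted
number
nurse
nurses
obj
occasional
occasionally
of
offer
offered
often
old
older
on
one
ongo
ongoing
open
opened
osteoarthritis
osteoporosis
overall
package
pad
pain
painful
paranoid
paraplegia
parkinson
past
patient
payment
payments
pension
people
per
person
personal
physical
place
plan
pleasant
pneumonia
poor
positive
poss
prefer
preferred
present
presentable
presents
pressure
previous
pride
primary
problem
prompt
prompted
provide
provided
provider
psoriasis
radio
rare
rash
receive
received
recent
record
recorded
reduc
reduced
refer
referral
refuse
refused
refusing
regular
reluctant
remain
remained
remains
remember
report
reported
reports
require
required
requires
resident
resistant
retire
retired
retiring
return
returned
review
reviewed
reviewing
risk
road
rude
sad
safe
safety
saw
schizophrenia
sciatica
scoliosis
scruffy
see
seem
seemed
sepsis
service
services
settl
settled
several
severe
she
shingle
shingles
shoe
shop
shopping
shops
short
shower
sight
significant
sister
situation
skin
sleep
sleeping
slight
slim
small
smith
social
society
sock
some
somewhat
son
sore
speak
speaking
stable
staff
stair
stairs
start
started
state
stated
status
stay
stayed
stenosis
stick
stock
stocked
stop
stopped
street
strength
stroke
struggle
struggled
struggling
stubborn
subj
sudden
sugar
support
supported
supportive
surname
swallow
swallowing
symptom
tablet
take
taken
takes
talk
talking
tea
teacher
teeth
television
tell
tenancy
term
text
the
there
thin
think
thought
thrombosis
through
tidy
time
times
tinnitus
tir
tired
title
to
toilet
told
took
tooth
total
toward
towards
town
transfer
transfers
two
ulcer
unable
uncooperative
unhappy
unkempt
unsafe
unstable
untidy
unwell
unwise
usually
vertigo
very
view
views
visit
visited
visits
vocal
walk
walked
walking
wander
wandering
ward
warm
was
wash
washing
watch
watches
water
weak
weakness
wear
week
weekend
weekly
weight
welcom
welcoming
well
wellbe
wellbeing
wheelchair
when
which
white
who
wife
will
wish
wishes
with
without
woman
wore
work
worked
worker
workers
worn
worri
worried
wound
year
years
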