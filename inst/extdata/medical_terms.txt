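dementia
alzheimer
diabetes
delirium
depression
anxiety
stroke
parkinson
arthritis
osteoporosis
hypertension
copd
asthma
epilepsy
schizophrenia
cancer
incontinence
cataract
glaucoma
gout
eczema
psoriasis
anaemia
angina
bronchitis
pneumonia
sepsis
cellulitis
shingles
sciatica
neuropathy
nephropathy
cirrhosis
hepatitis
hypothyroidism
hyperthyroidism
fibromyalgia
lymphoedema
vertigo
tinnitus
insomnia
constipation
dysphagia
aphasia
paraplegia
hemiplegia
scoliosis
stenosis
thrombosis
embolism
aneurysm
osteoarthritis
emphysema
melanoma
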