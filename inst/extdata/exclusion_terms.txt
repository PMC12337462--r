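mastectomy
hysterectomy
domestic violence
domestic abuse
prostate
ovarian
testicular
cervical
breast cancer
pregnancy
pregnant
menopause
miscarriage
gynaecological
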