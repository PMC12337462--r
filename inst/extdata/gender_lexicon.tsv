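female_form	male_form	match_kind
mrs	mr	title
ms	mr	title
miss	mr	title
her	his	pos_disambiguated
her	him	pos_disambiguated
she	he	exact
hers	his	exact
herself	himself	exact
woman	man	exact
women	men	exact
female	male	exact
females	males	exact
lady	gentleman	exact
ladies	gentlemen	exact
girl	boy	exact
girls	boys	exact
mother	father	exact
mothers	fathers	exact
mum	dad	exact
daughter	son	exact
daughters	sons	exact
sister	brother	exact
sisters	brothers	exact
wife	husband	exact
wives	husbands	exact
grandmother	grandfather	exact
grandma	grandpa	exact
granddaughter	grandson	exact
aunt	uncle	exact
aunts	uncles	exact
niece	nephew	exact
nieces	nephews	exact
widow	widower	exact
madam	sir	exact
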