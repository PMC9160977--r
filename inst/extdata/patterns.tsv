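pattern_id	mention_kind	pattern
aa3_hyphen	protein_substitution	(?i)(?<![A-Za-z0-9])(?<ref>{AA3})-(?<pos>[1-9][0-9]*)-(?<alt>{AA3})(?![A-Za-z0-9])
aa_full_hyphen	protein_substitution	(?i)(?<![A-Za-z0-9])(?<ref>{AAFULL})-(?<pos>[1-9][0-9]*)-(?<alt>{AAFULL})(?![A-Za-z0-9])
aa3_arrow	protein_substitution	(?i)(?<![A-Za-z0-9])(?<ref>{AA3})[- ]?(?<pos>[1-9][0-9]*)[ ]?(?:→|->)[ ]?(?<alt>{AA3})(?![A-Za-z0-9])
aa1_arrow	protein_substitution	(?<![A-Za-z0-9])(?<ref>{AA1})(?<pos>[1-9][0-9]*)[ ]?(?:→|->)[ ]?(?<alt>{AA1})(?![A-Za-z0-9])
aa3_concat	protein_substitution	(?i)(?<![A-Za-z0-9])(?<ref>{AA3})(?<pos>[1-9][0-9]*)(?<alt>{AA3})(?![A-Za-z0-9])
nonsense_stop	nonsense	(?<![A-Za-z0-9])(?<ref>{AA1})(?<pos>[1-9][0-9]*)(?<alt>\*|X)(?![A-Za-z0-9*])
aa1_basic	protein_substitution	(?<![A-Za-z0-9])(?<ref>{AA1})(?<pos>[1-9][0-9]*)(?<alt>{AA1})(?![A-Za-z0-9])
dna_cdot	dna_substitution	(?<![A-Za-z0-9])c\.(?<pos>[1-9][0-9]*)(?<ref>[ACGTU])>(?<alt>[ACGTU])(?![A-Za-z0-9])
dna_plain	dna_substitution	(?<![A-Za-z0-9.])(?<pos>[1-9][0-9]*)(?<ref>[ACGTU])>(?<alt>[ACGTU])(?![A-Za-z0-9])
prot_del	deletion	(?i)(?<![A-Za-z0-9])(?:p\.)?(?:{AA3}|{AA1})?(?<pos>[1-9][0-9]*)(?:_(?:{AA3}|{AA1})?[0-9]+)?[ ]?del(?:[A-Z]+)?(?![A-Za-z0-9])
prot_ins	insertion	(?i)(?<![A-Za-z0-9])(?:p\.)?(?:{AA3}|{AA1})?(?<pos>[1-9][0-9]*)(?:_(?:{AA3}|{AA1})?[0-9]+)?[ ]?ins(?:[A-Z]+)?(?![A-Za-z0-9])
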