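# Lexicon for screening free-text host values on generic-category records.
# A value counts as human if it parses to a taxid in human_taxids, or if it
# contains any positive token (case-insensitive substring) and no negative
# override. Negative overrides name non-human hosts so that strings like
# "humanized mouse" or "human gut microbiota transplanted into mice" are
# vetoed. Both lists are editable; every decision is logged in the scoping
# report for audit.
human_taxids: [9606, 63221, 741158]
positive_tokens:
  - human
  - homo sapiens
  - h. sapiens
  - patient
  - crew member
  - infant
  - adult
  - child
  - volunteer
  - subject
negative_overrides:
  - mouse
  - mice
  - mus musculus
  - murine
  - rat
  - rattus
  - pig
  - sus scrofa
  - porcine
  - bovine
  - bos taurus
  - cattle
  - canine
  - dog
  - canis
  - feline
  - felis
  - chicken
  - gallus
  - macaque
  - macaca
  - chimpanzee
  - pan troglodytes
  - gorilla
  - non-human
  - nonhuman
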