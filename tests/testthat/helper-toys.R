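# Tiny keys built from inline documents (also exercising the parser).

TOY_TWO_TAXON <- '{
  "title": "Two-taxon toy", "source": "test fixture", "root": 1,
  "couplets": [
    {"id": 1, "leads": [
      {"label": "a", "statement": "Corallum colonial",
       "taxon": {"genus": "Alpha", "regions": ["Atl."], "figure": "F1"}},
      {"label": "b", "statement": "Corallum solitary",
       "taxon": {"genus": "Beta", "regions": ["Pac."], "figure": "F2"}}
    ]}
  ]
}'

# A small polytomous key with one multiply keyed taxon (Gamma at 2b and 3a)
# and one taxon straight off the root.
TOY_MULTI <- '{
  "title": "Multi-path toy", "source": "test fixture", "root": 1,
  "couplets": [
    {"id": 1, "leads": [
      {"label": "a", "statement": "Wall porous", "next": 2},
      {"label": "b", "statement": "Wall solid", "next": 3},
      {"label": "c", "statement": "Wall absent",
       "taxon": {"genus": "Alpha", "regions": ["IWP"], "figure": "F1"}}
    ]},
    {"id": 2, "leads": [
      {"label": "a", "statement": "Columella present",
       "taxon": {"genus": "Beta", "regions": ["Atl."], "figure": "F2"}},
      {"label": "b", "statement": "Columella absent",
       "taxon": {"genus": "Gamma", "in_part": true,
                 "regions": ["Pac."], "figure": "F3"}}
    ]},
    {"id": 3, "leads": [
      {"label": "a", "statement": "Septa smooth",
       "taxon": {"genus": "Gamma", "in_part": true,
                 "regions": ["IP"], "figure": "F3"}},
      {"label": "b", "statement": "Septa dentate",
       "taxon": {"genus": "Delta", "subgenus": "Delta",
                 "regions": ["Ant."], "figure": "F4"}}
    ]}
  ]
}'

toy_two_taxon <- function() parse_key(TOY_TWO_TAXON)
toy_multi <- function() parse_key(TOY_MULTI)
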