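# Bundled fixtures

- `synthetic_s1_reference_table.tsv` — a **synthetic** stand-in for a curated
  reference annotation table of ketosynthase-alpha sequences. Accession ids
  and compound names are fabricated (`SYNREF*`, `synthetic_compound_*`); only
  the marginal structure is meaningful: 70 reference sequences of which 7
  encode spore pigments and 63 encode antibiotics spanning 20 distinct
  chemotypes. The extra columns (antibiotic name, chain length, first
  cyclization, priming unit) mirror the column layout such curated tables
  use; the loader only consumes `id`, `category` and `chemotype`.
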