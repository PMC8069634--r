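# External data

`potato_lcms.csv` (not distributed): the LC-MS potato tuber table used by
the case-study test in `tests/testthat/test-acceptance.R` — 62 samples x
1018 reconstructed metabolites, samples in rows, a `group` column with
labels `reference` (41 conventionally bred consumption varieties from
location A), `cisgenic`, `starch` and `other_location`, non-detects encoded
as 0.  It is study data distributed with the original publication and is not
shipped with this package; drop the file here (before installing) to enable
that test.
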