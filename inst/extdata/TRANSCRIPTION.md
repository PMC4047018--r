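# Canonical plain-text forms for published inputs

The published inputs this package consumes are distributed as
word-processor documents, which the package deliberately does not parse.
To run the full reproduction paths, transcribe them into the plain-text
forms below and place them in this directory.

## Character–taxon matrix (`published_hadrosauroid_matrix.nex`)

A NEXUS `DATA` block with the declared dimensions (61 taxa, 346
characters for the published analysis):

```
#NEXUS
BEGIN DATA;
  DIMENSIONS NTAX=61 NCHAR=346;
  FORMAT SYMBOLS="0 1 2 3 4 5" MISSING=? GAP=-;
  MATRIX
    Ouranosaurus_nigeriensis  0010?12...
    Zhanghenglong_yangchengensis  ?01{01}...
    ...
  ;
END;
```

Conventions enforced by the reader:

* taxon names: internal whitespace becomes `_`; quoted names allowed;
* one row per taxon (interleaved continuation rows are accepted);
* `?` and `-` both mean missing ("any state");
* polymorphic cells as `{01}` or `(01)` (TNT-style `[01]` in `xread`
  files, which `read_character_matrix(..., dialect = "tnt")` accepts);
* declared dimensions must match the body exactly — mismatches are hard
  errors naming the offending taxon or character.

Character indices are 1-based everywhere, so "character 7" in a
published character list is column 7 of the transcription.

## Measurement datasets

Delimited text (comma or tab) with header `taxon,attribute,specimen,value`,
one row per measured specimen, attribute ids `MA1` ... `MA6` (or
character numbers), ratios dimensionless, angles in degrees:

```
taxon,attribute,specimen,value
Zhanghenglong,MA6,V0014,0.50
...
```

`read_measurements()` averages multiple specimens per species before
clustering; the focal taxon is excluded from clustering by
`build_attribute_dataset(..., exclude = )`.
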