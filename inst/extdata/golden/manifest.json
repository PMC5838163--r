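{
  "package": "SEhierarchy",
  "version": "0.99.0",
  "inputs": {
    "peaks": "peaks.narrowPeak",
    "contacts": "contacts.tsv",
    "chromSizes": "chrom.sizes",
    "tss": "tss.bed",
    "variants": "variants.bed",
    "tads": "tads.bed",
    "ctcf": "ctcf.bed"
  },
  "parameters": {
    "resolution": 5000,
    "stitchGap": 12500,
    "L": 10000,
    "U": 2000000,
    "fdr": 0.01,
    "threshold": 1.5,
    "promoterFlank": 2000,
    "seed": 1,
    "backgroundMultiplier": 10
  },
  "results": {
    "nPeaks": 131,
    "nStitched": 72,
    "nSuper": 12,
    "nSignificant": 33,
    "nHierarchical": 5,
    "nHub": 5,
    "nNonHub": 26
  }
}
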