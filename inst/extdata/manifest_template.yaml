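# Standards manifest template. Synthetic example values; replace the file
# paths with your instrument's delimited exports.
filter:
  lower: 100
  upper: 1.0e7
standards:
  - name: AJH
    file: AJH.csv
  - name: ECL1
    file: ECL.csv
    replicate_of: ECL
    gate:
      FITC-H: [3.9, 4.9]
      SSC-H: [3.4, 4.4]
  - name: ECL2
    file: ECL.csv
    replicate_of: ECL
    gate:
      FITC-H: [4.5, 5.5]
      SSC-H: [4.0, 5.0]
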