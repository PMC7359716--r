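# ZymoBIOMICS Microbial Community Standard (D6300): manufacturer-declared
# theoretical 16S relative abundances of the eight bacterial members.
- taxon: Pseudomonas
  abundance: 4.6
  gram: negative
- taxon: Enterobacteriaceae_1
  abundance: 11.3
  gram: negative
- taxon: Enterobacteriaceae_2
  abundance: 10.0
  gram: negative
- taxon: Listeria
  abundance: 15.9
  gram: positive
- taxon: Staphylococcus
  abundance: 13.3
  gram: positive
- taxon: Lactobacillus
  abundance: 18.8
  gram: positive
- taxon: Enterococcus
  abundance: 10.4
  gram: positive
- taxon: Bacillus
  abundance: 15.7
  gram: positive
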