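# extdata

`cyp11b_pair_grch38.fa` (not bundled): to run the flagship site-catalog
check in `tests/testthat/test-acceptance.R`, place here a FASTA with the
two human paralog genomic sequences, gene A first:

1. CYP11B1, GRCh38 chr8:142876120-142879816
2. CYP11B2, GRCh38 chr8:142914143-142917843

The package does not redistribute human reference sequence; fetch the two
regions from any GRCh38 mirror (e.g. UCSC or Ensembl).
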