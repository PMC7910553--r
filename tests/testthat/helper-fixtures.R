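# Hand-built fixtures for the mapping-by-sequencing tests.

# Six-record toy for the filter cascade: record 1 passes every stage, the
# other five each fail exactly one stage (artifact, depth, GQ, mutant AF,
# azygous AF).
toy_records <- function() {
  pooled_variants(
    chrom = rep("Chr09", 6),
    pos = c(100, 200, 300, 400, 500, 600),
    ref = rep("G", 6), alt = rep("A", 6),
    wt_depth = rep(50, 6), wt_alt = rep(0, 6), wt_gq = rep(99, 6),
    az_depth = rep(60, 6),
    az_alt = c(20, 20, 20, 20, 20, 48),  # record 6: AF 0.8 > 0.5
    az_gq = rep(99, 6),
    mut_depth = c(50, 50, 5, 50, 50, 50),  # record 3: depth < 10
    mut_alt = c(50, 10, 5, 50, 40, 50),    # record 2: AF 0.2; record 5: AF 0.8
    mut_gq = c(99, 99, 99, 20, 99, 99)     # record 4: GQ < 30
  )
}

# A tiny plus- or minus-strand gene with 560 codons whose codon 552 is CGC
# (Arg), embedded in a synthetic chromosome with UTRs, one intron between
# two CDS exons, and intergenic flanks.
make_test_gene <- function(strand = "+", seed = 42) {
  fx <- simulate_gene_region(strand = strand, seed = seed,
                             gene_id = "abcg1_syn")
  fx$codon552_pos <- fx$pinned_codon_pos
  fx
}

# whole-CDS brute-force translator used as an oracle for classify_effect
translate_cds <- function(cds_seq) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds_seq),
                                     no.init.codon = TRUE))
}
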