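#' Simulate a gene region for effect-classification demos and tests
#'
#' Builds a fully synthetic chromosome segment carrying one protein-coding
#' gene: random intergenic flanks, 5' and 3' UTRs, and a CDS of
#' `n_codons` codons split across two exons by one intron. A chosen codon
#' can be pinned (by default codon 552 is `CGC`, arginine, so a first-base
#' C-to-A transversion yields the missense call R552S). The terminal codon
#' is a stop; all other codons are drawn stop-free so single-base edits
#' stay interpretable.
#'
#' @param strand `"+"` or `"-"` orientation of the gene on the chromosome.
#' @param seed Integer seed.
#' @param n_codons CDS length in codons (including the stop).
#' @param pinned_codon Codon index to pin.
#' @param pinned_value Codon (mRNA sense strand) placed at `pinned_codon`.
#' @param chrom Chromosome name.
#' @param gene_id Gene identifier.
#' @return A list with `genome` (named character vector of one chromosome),
#'   `model` (a [gene_model_lite()]), `cds_seq` (the spliced CDS, mRNA
#'   sense), and `pinned_codon_pos` (genomic positions of the pinned
#'   codon's three bases, in mRNA order).
#' @export
simulate_gene_region <- function(strand = "+", seed = 42, n_codons = 560,
                                 pinned_codon = 552, pinned_value = "CGC",
                                 chrom = "Chr09",
                                 gene_id = "synthetic.gene1") {
  stopifnot(strand %in% c("+", "-"), pinned_codon < n_codons)
  set.seed(seed)
  safe <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  codons <- sample(safe, n_codons, replace = TRUE)
  codons[pinned_codon] <- pinned_value
  codons[n_codons] <- "TAA"
  cds <- paste(codons, collapse = "")
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  upstream <- rand_seq(200)
  utr5 <- rand_seq(60)
  intron <- rand_seq(90)
  utr3 <- rand_seq(80)
  downstream <- rand_seq(150)
  exon1_len <- min(900, 3 * (n_codons - 1))  # split point inside the CDS
  cds1 <- substr(cds, 1, exon1_len)
  cds2 <- substr(cds, exon1_len + 1, nchar(cds))
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  off1 <- 3 * (pinned_codon - 1) + 1         # CDS offset of the pinned codon
  if (strand == "+") {
    chromseq <- paste0(upstream, utr5, cds1, intron, cds2, utr3, downstream)
    utr5_start <- nchar(upstream) + 1
    cds1_start <- utr5_start + nchar(utr5)
    cds2_start <- cds1_start + exon1_len + nchar(intron)
    utr3_start <- cds2_start + nchar(cds2)
    model <- gene_model_lite(
      gene_id, chrom, "+",
      cds = data.frame(start = c(cds1_start, cds2_start),
                       end = c(cds1_start + exon1_len - 1,
                               cds2_start + nchar(cds2) - 1)),
      utr = data.frame(start = c(utr5_start, utr3_start),
                       end = c(cds1_start - 1,
                               utr3_start + nchar(utr3) - 1)))
    codon_pos <- if (off1 > exon1_len)
      cds2_start + off1 - exon1_len - 1 + 0:2
    else cds1_start + off1 - 1 + 0:2
  } else {
    chromseq <- paste0(upstream, rc(utr3), rc(cds2), intron, rc(cds1),
                       rc(utr5), downstream)
    utr3_start <- nchar(upstream) + 1
    cds2_start <- utr3_start + nchar(utr3)
    cds1_start <- cds2_start + nchar(cds2) + nchar(intron)
    utr5_start <- cds1_start + exon1_len
    model <- gene_model_lite(
      gene_id, chrom, "-",
      cds = data.frame(start = c(cds2_start, cds1_start),
                       end = c(cds2_start + nchar(cds2) - 1,
                               cds1_start + exon1_len - 1)),
      utr = data.frame(start = c(utr3_start, utr5_start),
                       end = c(cds2_start - 1,
                               utr5_start + nchar(utr5) - 1)))
    codon_pos <- if (off1 > exon1_len)
      (cds2_start + nchar(cds2) - (off1 - exon1_len)) - 0:2
    else (cds1_start + exon1_len - off1) - 0:2
  }
  list(genome = stats::setNames(chromseq, chrom), model = model,
       cds_seq = cds, pinned_codon_pos = codon_pos)
}
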