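#' Minimal gene model
#'
#' Just enough annotation to classify point-mutation effects: ordered CDS
#' intervals (1-based, inclusive, genomic coordinates) and optional UTR
#' intervals. CDS intervals must be non-overlapping and sum to a multiple
#' of three.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds Data frame with columns `start`, `end` (1-based, inclusive).
#' @param utr Optional data frame with columns `start`, `end`.
#' @return An object of class `gene_model_lite`.
#' @export
gene_model_lite <- function(gene_id, chrom, strand = "+",
                            cds, utr = NULL) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(cds), all(c("start", "end") %in% names(cds)))
  cds <- cds[order(cds$start), , drop = FALSE]
  if (any(cds$end < cds$start)) stop("CDS interval with end < start")
  if (nrow(cds) > 1 && any(cds$start[-1] <= cds$end[-nrow(cds)]))
    stop("overlapping CDS intervals in ", gene_id, call. = FALSE)
  total <- sum(cds$end - cds$start + 1)
  if (total %% 3 != 0)
    stop("annotation error: CDS length of ", gene_id,
         " (", total, " bp) not divisible by 3", call. = FALSE)
  if (!is.null(utr)) utr <- utr[order(utr$start), , drop = FALSE]
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 cds = cds, utr = utr),
            class = "gene_model_lite")
}

gene_span <- function(gm) {
  ivs <- rbind(gm$cds[, c("start", "end")],
               if (!is.null(gm$utr)) gm$utr[, c("start", "end")])
  c(min(ivs$start), max(ivs$end))
}

in_intervals <- function(pos, ivs) {
  !is.null(ivs) && nrow(ivs) > 0 && any(pos >= ivs$start & pos <= ivs$end)
}

complement_base <- function(b) chartr("ACGTacgt", "TGCAtgca", b)

# concatenated CDS sequence in translation order (5' -> 3' of the mRNA)
cds_sequence <- function(gm, genome) {
  chromseq <- genome_sequence(genome, gm$chrom)
  pieces <- vapply(seq_len(nrow(gm$cds)), function(i)
    substr(chromseq, gm$cds$start[i], gm$cds$end[i]), character(1))
  s <- paste(pieces, collapse = "")
  if (gm$strand == "-")
    s <- complement_base(paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  s
}

genome_sequence <- function(genome, chrom) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (!chrom %in% names(genome))
    stop("chromosome ", chrom, " not in genome", call. = FALSE)
  genome[[chrom]]
}

# genomic position -> 1-based offset in the concatenated, stranded CDS
cds_offset <- function(gm, pos) {
  widths <- gm$cds$end - gm$cds$start + 1
  before <- cumsum(c(0, widths[-length(widths)]))
  i <- which(pos >= gm$cds$start & pos <= gm$cds$end)
  if (!length(i)) return(NA_integer_)
  off_plus <- before[i] + (pos - gm$cds$start[i] + 1)
  if (gm$strand == "+") off_plus else sum(widths) - off_plus + 1
}

#' Classify the coding effect of a point mutation
#'
#' Maps a SNP through a set of [gene_model_lite()] annotations: positions
#' outside every gene are `intergenic`; inside a UTR interval, `utr`;
#' inside an intron, `intron` (or `splice` within 2 bp of an exon edge);
#' inside the CDS the reference and mutant codons are translated and the
#' call is `synonymous`, `missense` (with an amino-acid change such as
#' `R552S`) or `nonsense` for a stop gain.
#'
#' @param record A list or one-row data frame with `chrom`, `pos`, `ref`,
#'   `alt` (single bases, plus-strand as in a VCF).
#' @param gene_models A list of [gene_model_lite()] objects.
#' @param genome Named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param codon_table Named character vector mapping codons to amino acids;
#'   defaults to the standard code (`Biostrings::GENETIC_CODE`).
#' @return A list with `category`, `gene_id`, and `aa_change` (`NA` unless
#'   the call is coding).
#' @export
classify_effect <- function(record, gene_models, genome,
                            codon_table = Biostrings::GENETIC_CODE) {
  pos <- as.integer(record$pos)
  chrom <- as.character(record$chrom)
  ref <- toupper(as.character(record$ref))
  alt <- toupper(as.character(record$alt))
  effect <- function(category, gene_id = NA_character_,
                     aa_change = NA_character_) {
    list(category = category, gene_id = gene_id, aa_change = aa_change)
  }
  for (gm in gene_models) {
    if (gm$chrom != chrom) next
    span <- gene_span(gm)
    if (pos < span[1] || pos > span[2]) next
    if (in_intervals(pos, gm$cds)) {
      off <- cds_offset(gm, pos)
      cds <- cds_sequence(gm, genome)
      ref_tx <- if (gm$strand == "+") ref else complement_base(ref)
      alt_tx <- if (gm$strand == "+") alt else complement_base(alt)
      if (substr(cds, off, off) != ref_tx)
        stop("reference allele mismatch at ", chrom, ":", pos, call. = FALSE)
      codon_i <- (off - 1L) %/% 3L + 1L
      codon_from <- substr(cds, 3 * codon_i - 2, 3 * codon_i)
      codon_to <- codon_from
      substr(codon_to, (off - 1L) %% 3L + 1L, (off - 1L) %% 3L + 1L) <- alt_tx
      aa_from <- codon_table[[codon_from]]
      aa_to <- codon_table[[codon_to]]
      change <- paste0(aa_from, codon_i, aa_to)
      cat_call <- if (aa_from == aa_to) "synonymous"
      else if (aa_to == "*") "nonsense" else "missense"
      return(effect(cat_call, gm$gene_id, change))
    }
    if (in_intervals(pos, gm$utr)) return(effect("utr", gm$gene_id))
    # inside the gene span but in no exon interval: intronic
    exons <- rbind(gm$cds[, c("start", "end")],
                   if (!is.null(gm$utr)) gm$utr[, c("start", "end")])
    near_edge <- any(pos >= exons$start - 2 & pos < exons$start |
                       pos > exons$end & pos <= exons$end + 2)
    return(effect(if (near_edge) "splice" else "intron", gm$gene_id))
  }
  effect("intergenic")
}

#' Read minimal gene models from GFF3
#'
#' Reads `gene`, `CDS` and UTR features (types containing `UTR`) from a
#' GFF3 file via `rtracklayer::readGFF` and assembles one
#' [gene_model_lite()] per gene, using the `Parent`/`ID` attributes to
#' group features.
#'
#' @param path GFF3 file.
#' @return A named list of [gene_model_lite()] objects.
#' @export
read_gene_models <- function(path) {
  f <- as.data.frame(rtracklayer::readGFF(path))
  parent1 <- vapply(f$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  genes <- f[f$type == "gene", , drop = FALSE]
  models <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    kids <- f[!is.na(parent1) & parent1 == gid, , drop = FALSE]
    cds <- kids[kids$type == "CDS", c("start", "end"), drop = FALSE]
    utr <- kids[grepl("UTR", kids$type, ignore.case = TRUE),
                c("start", "end"), drop = FALSE]
    models[[gid]] <- gene_model_lite(gid, as.character(genes$seqid[i]),
                                     as.character(genes$strand[i]),
                                     cds = cds,
                                     utr = if (nrow(utr)) utr else NULL)
  }
  models
}

#' Write minimal gene models as GFF3
#'
#' @param models A list of [gene_model_lite()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  out <- c("##gff-version 3")
  for (gm in models) {
    span <- gene_span(gm)
    out <- c(out, paste(gm$chrom, "c4leak", "gene", span[1], span[2], ".",
                        gm$strand, ".", paste0("ID=", gm$gene_id),
                        sep = "\t"))
    for (i in seq_len(nrow(gm$cds)))
      out <- c(out, paste(gm$chrom, "c4leak", "CDS", gm$cds$start[i],
                          gm$cds$end[i], ".", gm$strand, "0",
                          paste0("Parent=", gm$gene_id), sep = "\t"))
    if (!is.null(gm$utr))
      for (i in seq_len(nrow(gm$utr)))
        out <- c(out, paste(gm$chrom, "c4leak", "UTR", gm$utr$start[i],
                            gm$utr$end[i], ".", gm$strand, ".",
                            paste0("Parent=", gm$gene_id), sep = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}
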