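#' Write a three-pool variant table as VCF 4.2
#'
#' Emits one multi-sample VCF with `GT:AD:DP:GQ` per pool. Genotypes are
#' coarse calls from the pool allele frequency (0/0 below 0.25, 1/1 above
#' 0.75, 0/1 between, ./. at zero depth); the allele-depth (`AD`), depth
#' (`DP`) and genotype-quality (`GQ`) fields carry the pooled counts the
#' downstream filter uses.
#'
#' @param variants A [pooled_variants()] data frame.
#' @param path Output file.
#' @param sample_names Names of the wildtype, azygous and mutant pool
#'   columns, in that order.
#' @param contig_length Optional contig length for the header.
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(variants, path,
                           sample_names = c("WT_pool", "AZ_pool", "MUT_pool"),
                           contig_length = NULL) {
  stopifnot(length(sample_names) == 3)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=c4leak",
           if (!is.null(contig_length))
             sprintf("##contig=<ID=%s,length=%d>", variants$chrom[1],
                     as.integer(contig_length)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_names), collapse = "\t"))
  fmt_sample <- function(depth, alt, gq) {
    af <- ifelse(depth > 0, alt / depth, NA_real_)
    gt <- ifelse(is.na(af), "./.",
                 ifelse(af > 0.75, "1/1", ifelse(af >= 0.25, "0/1", "0/0")))
    sprintf("%s:%d,%d:%d:%d", gt, depth - alt, alt, depth, gq)
  }
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", ".", "GT:AD:DP:GQ",
                fmt_sample(variants$wt_depth, variants$wt_alt, variants$wt_gq),
                fmt_sample(variants$az_depth, variants$az_alt, variants$az_gq),
                fmt_sample(variants$mut_depth, variants$mut_alt,
                           variants$mut_gq),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a three-pool VCF into a variant table
#'
#' Reads a VCF 4.x with `vcfR`, extracts per-sample `AD`, `DP` and `GQ`,
#' and maps the named samples onto the wildtype / azygous / mutant pools.
#'
#' @param path VCF file.
#' @param wt,azygous,mutant Sample names of the three pools.
#' @return A [pooled_variants()] data frame.
#' @export
read_pool_vcf <- function(path, wt = "WT_pool", azygous = "AZ_pool",
                          mutant = "MUT_pool") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  for (nm in c(wt, azygous, mutant))
    if (!nm %in% samples)
      stop("sample '", nm, "' not found in ", path,
           " (has: ", paste(samples, collapse = ", "), ")", call. = FALSE)
  ad <- vcfR::extract.gt(v, "AD")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, "GQ", as.numeric = TRUE)
  alt_of <- function(s) as.integer(vapply(strsplit(ad[, s], ","),
                                          `[`, "", 2))
  fix <- vcfR::getFIX(v)
  pooled_variants(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                  ref = fix[, "REF"], alt = fix[, "ALT"],
                  wt_depth = dp[, wt], wt_alt = alt_of(wt), wt_gq = gq[, wt],
                  az_depth = dp[, azygous], az_alt = alt_of(azygous),
                  az_gq = gq[, azygous],
                  mut_depth = dp[, mutant], mut_alt = alt_of(mutant),
                  mut_gq = gq[, mutant])
}

#' Write the candidate table as TSV
#'
#' @param candidates A [pooled_variants()] data frame (e.g. the
#'   `candidates` element of [filter_variants()]), optionally with `effect`
#'   and `gene` columns added.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  utils::write.table(as.data.frame(candidates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a filter audit as JSON
#'
#' @param audit The `audit` element of [filter_variants()].
#' @param path Optional file; if `NULL` the JSON string is returned.
#' @param thresholds The [filter_thresholds()] used (recorded alongside).
#' @param seed Optional seed to record.
#' @return JSON string (invisibly when written to `path`).
#' @export
write_audit_json <- function(audit, path = NULL, thresholds = NULL,
                             seed = NULL) {
  rec <- list(audit = as.list(audit))
  if (!is.null(thresholds)) rec$thresholds <- unclass(thresholds)
  if (!is.null(seed)) rec$seed <- seed
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
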