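#' Per-pool allele frequency
#'
#' `alt_count / depth`, with zero depth returning `NA` (an undefined
#' marker), never 0.
#'
#' @param alt_count Alternate-allele read count.
#' @param depth Total read depth (>= 0).
#' @return Allele frequency in `[0, 1]`, or `NA` at zero depth.
#' @export
pool_allele_frequency <- function(alt_count, depth) {
  if (any(depth < 0)) stop("depth must be >= 0", call. = FALSE)
  if (any(alt_count > depth))
    stop("alt_count exceeds depth", call. = FALSE)
  ifelse(depth > 0, alt_count / depth, NA_real_)
}

#' Filter thresholds of the candidate-mutation cascade
#'
#' Defaults match the published cascade: variants with mutant-pool allele
#' frequency at or below 0.3 are treated as alignment artifacts; surviving
#' variants need at least 10 mutant-pool reads and genotype quality 30; a
#' causal candidate must be fixed in the mutant pool (frequency 1, epsilon
#' 0), at frequency at most 0.5 in the azygous pool, and absent from the
#' wildtype pool.
#'
#' @param min_af_artifact Mutant-pool AF at or below this is an artifact.
#' @param min_depth Minimum mutant-pool read depth.
#' @param min_gq Minimum mutant-pool genotype quality (phred).
#' @param mutant_af_target Required mutant-pool AF (with `mutant_af_epsilon`
#'   tolerance for sampling noise).
#' @param mutant_af_epsilon Tolerance below `mutant_af_target`.
#' @param max_azygous_af Maximum azygous-pool AF.
#' @param max_wt_af Maximum wildtype-pool AF (with `wt_af_epsilon`).
#' @param wt_af_epsilon Tolerance above `max_wt_af`.
#' @param artifact_pools Pools the artifact filter applies to
#'   (default mutant only; `c("mut", "az", "wt")` applies it to all).
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_af_artifact = 0.3, min_depth = 10,
                              min_gq = 30, mutant_af_target = 1.0,
                              mutant_af_epsilon = 0, max_azygous_af = 0.5,
                              max_wt_af = 0, wt_af_epsilon = 0,
                              artifact_pools = "mut") {
  stopifnot(min_af_artifact >= 0, min_af_artifact <= 1,
            min_depth >= 0, min_gq >= 0,
            mutant_af_target >= 0, mutant_af_target <= 1,
            mutant_af_epsilon >= 0, max_azygous_af >= 0, max_azygous_af <= 1,
            max_wt_af >= 0, max_wt_af <= 1, wt_af_epsilon >= 0,
            all(artifact_pools %in% c("mut", "az", "wt")))
  structure(list(min_af_artifact = min_af_artifact, min_depth = min_depth,
                 min_gq = min_gq, mutant_af_target = mutant_af_target,
                 mutant_af_epsilon = mutant_af_epsilon,
                 max_azygous_af = max_azygous_af, max_wt_af = max_wt_af,
                 wt_af_epsilon = wt_af_epsilon,
                 artifact_pools = artifact_pools),
            class = "filter_thresholds")
}

#' Three-pool variant table
#'
#' Builds the pooled variant table consumed by [filter_variants()]: one row
#' per variant with per-pool depth, alternate-read count, allele frequency
#' and genotype quality for the wildtype (`wt`), azygous (`az`) and mutant
#' (`mut`) pools. Allele frequencies are derived from the counts.
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles.
#' @param wt_depth,wt_alt,wt_gq Wildtype-pool depth, alt count, GQ.
#' @param az_depth,az_alt,az_gq Azygous-pool depth, alt count, GQ.
#' @param mut_depth,mut_alt,mut_gq Mutant-pool depth, alt count, GQ.
#' @return A data frame of class `pooled_variants`.
#' @export
pooled_variants <- function(chrom, pos, ref, alt,
                            wt_depth, wt_alt, wt_gq,
                            az_depth, az_alt, az_gq,
                            mut_depth, mut_alt, mut_gq) {
  if (any(pos < 1)) stop("pos must be >= 1", call. = FALSE)
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   wt_depth = wt_depth, wt_alt = wt_alt,
                   wt_af = pool_allele_frequency(wt_alt, wt_depth),
                   wt_gq = wt_gq,
                   az_depth = az_depth, az_alt = az_alt,
                   az_af = pool_allele_frequency(az_alt, az_depth),
                   az_gq = az_gq,
                   mut_depth = mut_depth, mut_alt = mut_alt,
                   mut_af = pool_allele_frequency(mut_alt, mut_depth),
                   mut_gq = mut_gq,
                   stringsAsFactors = FALSE)
  structure(df, class = c("pooled_variants", "data.frame"))
}

#' Candidate-mutation filter cascade
#'
#' Applies the published cascade in order: (1) drop artifact-like variants
#' (mutant-pool AF at or below `min_af_artifact`); (2) require mutant-pool
#' depth and genotype quality; (3) require fixation in the mutant pool;
#' (4) require azygous-pool AF at or below `max_azygous_af`; (5) require
#' absence from the wildtype pool. Records whose allele frequency is
#' undefined (zero depth) at a required stage are dropped with audit reason
#' `no_coverage`. The audit reports removals per stage; candidates are
#' returned sorted by `(chrom, pos)`.
#'
#' @param records A [pooled_variants()] data frame.
#' @param thresholds A [filter_thresholds()] object.
#' @return A list with `candidates` (a `pooled_variants` subset) and
#'   `audit` (named integer vector of per-stage removals, plus `input` and
#'   `passed`).
#' @export
filter_variants <- function(records, thresholds = filter_thresholds()) {
  stopifnot(inherits(records, "pooled_variants") || is.data.frame(records))
  th <- thresholds
  audit <- c(no_coverage = 0L, artifact = 0L, depth_gq = 0L,
             mutant_af = 0L, azygous_af = 0L, wt_af = 0L)
  keep <- rep(TRUE, nrow(records))
  drop_stage <- function(keep, fail, stage) {
    fail <- fail & keep
    audit[stage] <<- audit[stage] + sum(fail)
    keep & !fail
  }
  if (nrow(records) > 0) {
    af_for <- function(pool) records[[paste0(pool, "_af")]]
    # stage 1: alignment-artifact frequencies
    for (pool in th$artifact_pools) {
      af <- af_for(pool)
      keep <- drop_stage(keep, is.na(af), "no_coverage")
      keep <- drop_stage(keep, !is.na(af) & af <= th$min_af_artifact,
                         "artifact")
    }
    # stage 2: mutant-pool depth and genotype quality
    keep <- drop_stage(keep, records$mut_depth < th$min_depth |
                         records$mut_gq < th$min_gq, "depth_gq")
    # stage 3: fixed in the mutant pool
    keep <- drop_stage(keep, is.na(records$mut_af), "no_coverage")
    keep <- drop_stage(keep,
                       !is.na(records$mut_af) &
                         records$mut_af < th$mutant_af_target - th$mutant_af_epsilon,
                       "mutant_af")
    # stage 4: heterozygous-or-absent in the azygous pool
    keep <- drop_stage(keep, is.na(records$az_af), "no_coverage")
    keep <- drop_stage(keep, !is.na(records$az_af) &
                         records$az_af > th$max_azygous_af, "azygous_af")
    # stage 5: absent from the wildtype pool (induced, not background)
    keep <- drop_stage(keep, is.na(records$wt_af), "no_coverage")
    keep <- drop_stage(keep, !is.na(records$wt_af) &
                         records$wt_af > th$max_wt_af + th$wt_af_epsilon,
                       "wt_af")
  }
  cand <- records[keep, , drop = FALSE]
  cand <- cand[order(cand$chrom, cand$pos), , drop = FALSE]
  rownames(cand) <- NULL
  audit <- c(audit, input = nrow(records), passed = nrow(cand))
  list(candidates = structure(cand,
                              class = c("pooled_variants", "data.frame")),
       audit = audit)
}

#' Mutant-pool allele-frequency landscape along chromosomes
#'
#' Averages the mutant-pool allele frequency in non-overlapping windows of
#' `window_bp` along each chromosome; the causal locus shows as a peak of
#' near-fixed frequencies with a linkage decay around it. Windows without
#' variants are kept with `NA` mean. Peak windows (ties included) are
#' attached as the `peaks` attribute and returned in the list.
#'
#' @param records A [pooled_variants()] data frame.
#' @param window_bp Window size in bp (> 0).
#' @return A list with `landscape` (chrom, window_start, window_end,
#'   n_variants, mean_af) and `peaks` (the rows attaining the maximum
#'   mean frequency; several rows when tied).
#' @export
af_landscape <- function(records, window_bp = 1e6) {
  if (window_bp <= 0) stop("window_bp must be > 0", call. = FALSE)
  out <- list()
  for (chr in unique(records$chrom)) {
    rec <- records[records$chrom == chr, , drop = FALSE]
    last <- max(rec$pos)
    starts <- seq(1, last, by = window_bp)
    idx <- findInterval(rec$pos, starts)
    mean_af <- vapply(seq_along(starts), function(i) {
      af <- rec$mut_af[idx == i]
      af <- af[!is.na(af)]
      if (length(af)) mean(af) else NA_real_
    }, numeric(1))
    n_var <- vapply(seq_along(starts), function(i) sum(idx == i), integer(1))
    out[[chr]] <- data.frame(chrom = chr, window_start = starts,
                             window_end = starts + window_bp - 1,
                             n_variants = n_var, mean_af = mean_af,
                             stringsAsFactors = FALSE)
  }
  landscape <- do.call(rbind, out)
  rownames(landscape) <- NULL
  if (all(is.na(landscape$mean_af))) {
    peaks <- landscape[0, , drop = FALSE]
  } else {
    top <- max(landscape$mean_af, na.rm = TRUE)
    peaks <- landscape[!is.na(landscape$mean_af) &
                         landscape$mean_af == top, , drop = FALSE]
  }
  list(landscape = landscape, peaks = peaks)
}

#' Exact Mendelian pool-frequency expectations
#'
#' For a recessive single-locus cross (heterozygous F1 selfed, pools drawn
#' from BC1F2 phenotype classes), enumerates the monohybrid genotype classes
#' (1 AA : 2 Aa : 1 aa) and returns the expected mutant-allele frequency in
#' a pool. The mutant pool conditions on the recessive phenotype (all `aa`,
#' frequency 1); the azygous pool mixes 1 AA : 2 Aa (frequency 1/3); the
#' wildtype pool carries no induced alleles. An unlinked induced site is
#' heterozygous in the F1, hence at frequency 1/2 among all F2-derived
#' pools and absent from the wildtype pool.
#'
#' @param design A [cross_design()] (recessive single-locus designs only).
#' @param pool `"mutant"`, `"azygous"`, or `"wt"`.
#' @param site `"causal"` or `"unlinked"`.
#' @return Expected allele frequency.
#' @export
expected_pool_frequency <- function(design = cross_design(),
                                    pool = c("mutant", "azygous", "wt"),
                                    site = c("causal", "unlinked")) {
  pool <- match.arg(pool)
  site <- match.arg(site)
  if (!inherits(design, "cross_design"))
    stop("unsupported design", call. = FALSE)
  if (pool == "wt") return(0)
  # enumerate the selfed-F1 genotype classes: copies of the mutant allele
  # at the queried site, with class weights 1:2:1
  copies <- c(0, 1, 2)
  weight <- c(1, 2, 1)
  if (site == "causal") {
    in_pool <- if (pool == "mutant") copies == 2 else copies < 2
    sum(weight[in_pool] * copies[in_pool]) / (2 * sum(weight[in_pool]))
  } else {
    # unlinked: genotype at the site independent of the phenotype class,
    # so conditioning does not change the 1:2:1 mixture
    sum(weight * copies) / (2 * sum(weight))
  }
}
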