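#' Measurement-noise model for the synthetic generators
#'
#' @param a_sd Gaussian standard deviation added to assimilation
#'   (umol m-2 s-1).
#' @param delta_sd Gaussian standard deviation added to 13C discrimination
#'   (per mil).
#' @param depth_mean Poisson mean of per-pool sequencing depth (reads).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(a_sd = 0.5, delta_sd = 0.2, depth_mean = 50) {
  stopifnot(a_sd >= 0, delta_sd >= 0, depth_mean > 0)
  structure(list(a_sd = a_sd, delta_sd = delta_sd, depth_mean = depth_mean),
            class = "noise_model")
}

#' Backcross/self and pooling design of the mapping population
#'
#' Defaults reproduce the study design: a homozygous mutant crossed to
#' wildtype, the F1 selfed into a BC1F2 of 300 plants, with 45 phenotyped
#' mutants, 54 azygous/hemizygous segregants and 50 separate wildtype
#' plants pooled for sequencing. One chromosome pair carries the induced
#' mutations; recombination uses the Haldane map function without
#' interference.
#'
#' @param n_f2 BC1F2 population size.
#' @param pool_mutant,pool_azygous,pool_wt Pool sizes (individuals).
#' @param n_induced Number of induced heterozygous mutations in the F1
#'   (besides the causal one).
#' @param chrom Chromosome name.
#' @param chrom_bp Physical length (bp).
#' @param chrom_cm Genetic length (centimorgans).
#' @param causal_pos Physical position of the causal locus (bp).
#' @param depth_mean Mean per-pool sequencing depth (reads).
#' @param misclassification Probability that an individual's phenotype call
#'   is flipped before pooling (0 = perfect phenotyping).
#' @return An object of class `cross_design`.
#' @export
cross_design <- function(n_f2 = 300, pool_mutant = 45, pool_azygous = 54,
                         pool_wt = 50, n_induced = 60,
                         chrom = "Chr09", chrom_bp = 50e6, chrom_cm = 150,
                         causal_pos = 20e6, depth_mean = 50,
                         misclassification = 0) {
  stopifnot(n_f2 >= 1, pool_mutant >= 1, pool_azygous >= 1, pool_wt >= 1,
            n_induced >= 0, chrom_bp > 0, chrom_cm > 0,
            causal_pos >= 1, causal_pos <= chrom_bp, depth_mean > 0,
            misclassification >= 0, misclassification < 1)
  structure(list(n_f2 = n_f2, pool_mutant = pool_mutant,
                 pool_azygous = pool_azygous, pool_wt = pool_wt,
                 n_induced = n_induced, chrom = chrom, chrom_bp = chrom_bp,
                 chrom_cm = chrom_cm, causal_pos = causal_pos,
                 depth_mean = depth_mean,
                 misclassification = misclassification),
            class = "cross_design")
}

#' Simulate replicated gas-exchange curves from the forward model
#'
#' Evaluates the forward C4 model over a grid and adds iid Gaussian noise
#' to the assimilation rates. The noiseless model curve and the generating
#' parameters are kept in the `truth` attribute of each replicate.
#'
#' @param params A [c4_parameters()] object.
#' @param grid CO2 grid (ubar) for `kind = "aci"`, irradiance grid for
#'   `kind = "light"`.
#' @param noise A [noise_model()].
#' @param n_replicates Number of replicate curves.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param kind `"aci"` or `"light"`.
#' @param irradiance Irradiance for CO2-response curves.
#' @param cm CO2 for light-response curves (ubar).
#' @param label Label stored on each curve.
#' @return A list of [gas_exchange_curve()] objects.
#' @export
simulate_gas_exchange <- function(params, grid = c(0, 50, 75, 100, 200, 300,
                                                   400, 600, 800, 1000, 1200),
                                  noise = noise_model(), n_replicates = 1,
                                  seed = 1, kind = c("aci", "light"),
                                  irradiance = 1500, cm = 0.41 * 380,
                                  label = "simulated") {
  kind <- match.arg(kind)
  set.seed(seed)
  truth <- if (kind == "aci") aci_curve(params, grid, irradiance)
  else light_curve(params, grid, cm)
  lapply(seq_len(n_replicates), function(r) {
    a_obs <- truth$a_net + stats::rnorm(nrow(truth), 0, noise$a_sd)
    cv <- gas_exchange_curve(ci = truth$ci_ubar, a_net = a_obs,
                             irradiance = truth$irradiance,
                             label = sprintf("%s rep%d", label, r))
    attr(cv, "truth") <- truth
    cv
  })
}

#' Simulate a PEPC-inhibited (DCDP-fed) CO2-response curve
#'
#' Forces the C4 cycle off (`vpmax = 0`, so PEP carboxylation is zero) and
#' evaluates the enzyme-limited model over a low-Ci grid: CO2 then reaches
#' the bundle sheath only by diffusion and the initial slope of the curve
#' approximates `gbs`, while bundle-sheath Rubisco retains some residual
#' fixation.
#'
#' @inheritParams simulate_gas_exchange
#' @param grid CO2 grid (ubar), low-Ci range.
#' @return A [gas_exchange_curve()] labelled `"DCDP-fed"`, with the
#'   noiseless truth as attribute.
#' @export
simulate_dcdp_curve <- function(params, grid = c(0, 50, 75, 100, 200, 300,
                                                 400),
                                noise = noise_model(a_sd = 0), seed = 1,
                                label = "DCDP-fed") {
  set.seed(seed)
  inhibited <- update_parameters(params, vpmax = 0, vpr = 0)
  truth <- aci_curve(inhibited, grid, irradiance = 1500)
  a_obs <- truth$a_net + stats::rnorm(nrow(truth), 0, noise$a_sd)
  cv <- gas_exchange_curve(ci = truth$ci_ubar, a_net = a_obs, label = label)
  attr(cv, "truth") <- truth
  attr(cv, "true_gbs_mmol") <- 1000 * params$gbs
  cv
}

#' Simulate isotope-discrimination observations at a known leakiness
#'
#' Forward discrimination (the linear leakiness relation) plus Gaussian
#' noise on delta.
#'
#' @param true_phi True leakiness, in `[0, 1)`.
#' @param ci_over_ca Vector of Ci/Ca ratios, one per observation.
#' @param noise A [noise_model()] (only `delta_sd` is used).
#' @param seed Integer seed.
#' @param ca Ambient CO2 (ubar).
#' @param constants An [isotope_constants()] object.
#' @return An [isotope_observations()] data frame with a `true_phi`
#'   attribute.
#' @export
simulate_discrimination <- function(true_phi, ci_over_ca,
                                    noise = noise_model(), seed = 1,
                                    ca = 380,
                                    constants = isotope_constants()) {
  if (true_phi < 0 || true_phi >= 1)
    stop("true_phi must lie in [0, 1)", call. = FALSE)
  set.seed(seed)
  delta <- discrimination_from_leakiness(true_phi, ci_over_ca, constants) +
    stats::rnorm(length(ci_over_ca), 0, noise$delta_sd)
  obs <- isotope_observations(delta, ci_over_ca, ca)
  attr(obs, "true_phi") <- true_phi
  obs
}

# haldane map function: recombination fraction from distance in morgans
haldane_r <- function(morgans) 0.5 * (1 - exp(-2 * morgans))

# gametes from an F1 whose two homologues are 'all mutant' vs 'all
# wildtype': a gamete is a mosaic determined by crossovers between
# adjacent marker positions. Returns an n_gametes x n_markers 0/1 matrix
# (1 = mutant allele).
f1_gametes <- function(n_gametes, pos_bp, chrom_bp, chrom_cm) {
  n_mark <- length(pos_bp)
  d_morgans <- diff(pos_bp) / chrom_bp * chrom_cm / 100
  r <- haldane_r(d_morgans)
  strand <- matrix(0L, n_gametes, n_mark)
  strand[, 1] <- stats::rbinom(n_gametes, 1, 0.5)
  if (n_mark > 1) {
    switches <- matrix(stats::rbinom(n_gametes * (n_mark - 1), 1,
                                     rep(r, each = n_gametes)),
                       n_gametes, n_mark - 1)
    strand[, -1] <- (strand[, 1] + t(apply(switches, 1, cumsum))) %% 2
  }
  strand
}

#' Simulate BC1F2 genotypes at the induced-mutation markers
#'
#' Places the induced mutations uniformly along one chromosome pair (the
#' causal site at its designed position), generates each F2 individual
#' from two independent F1 gametes with Haldane recombination, and calls
#' the phenotype from homozygosity at the causal locus.
#'
#' @param design A [cross_design()].
#' @param seed Integer seed.
#' @return A list with `pos` (marker positions, bp), `causal_index`,
#'   `genotypes` (n_f2 x n_markers matrix of mutant-allele counts 0/1/2),
#'   and `phenotype` (logical, mutant phenotype).
#' @export
simulate_cross <- function(design = cross_design(), seed = 1) {
  stopifnot(inherits(design, "cross_design"))
  set.seed(seed)
  pos <- sort(sample.int(design$chrom_bp, design$n_induced))
  pos <- sort(unique(c(pos, design$causal_pos)))
  causal_index <- match(design$causal_pos, pos)
  g1 <- f1_gametes(design$n_f2, pos, design$chrom_bp, design$chrom_cm)
  g2 <- f1_gametes(design$n_f2, pos, design$chrom_bp, design$chrom_cm)
  geno <- g1 + g2
  phenotype <- geno[, causal_index] == 2L
  list(pos = pos, causal_index = causal_index, genotypes = geno,
       phenotype = phenotype)
}

# NMU mutation spectrum: mostly G:C -> A:T transitions
draw_ref_alt <- function(n, gc_at_bias = 0.8) {
  ref <- alt <- character(n)
  is_gc <- stats::runif(n) < gc_at_bias
  gc_strand <- stats::runif(n) < 0.5
  ref[is_gc] <- ifelse(gc_strand[is_gc], "G", "C")
  alt[is_gc] <- ifelse(gc_strand[is_gc], "A", "T")
  other <- which(!is_gc)
  for (i in other) {
    ref[i] <- sample(c("A", "T", "G", "C"), 1)
    alt[i] <- sample(setdiff(c("A", "T", "G", "C"), ref[i]), 1)
  }
  list(ref = ref, alt = alt)
}

#' Simulate the three sequenced pools of a BC1F2 mapping experiment
#'
#' Runs [simulate_cross()], draws the mutant and azygous pools without
#' replacement from the phenotype classes (optionally with phenotyping
#' errors), adds a wildtype pool that carries no induced alleles, and
#' samples per-variant reads: depth Poisson around the design mean,
#' alternate reads binomial at the pool allele frequency. Genotype quality
#' is synthesized as an increasing function of depth
#' (`GQ = min(99, round(4.3 * depth))` -- a plumbing surrogate, not a
#' caller's likelihood).
#'
#' @param design A [cross_design()].
#' @param seed Integer seed.
#' @return A list with `variants` (a [pooled_variants()] data frame) and
#'   `truth` (marker positions, causal index/position, true per-pool allele
#'   frequencies, individual genotypes, phenotype vector).
#' @export
simulate_bc1f2_pools <- function(design = cross_design(), seed = 1) {
  cross <- simulate_cross(design, seed = seed)
  # continue the seeded stream for pooling and read sampling
  n_mark <- length(cross$pos)
  pheno <- cross$phenotype
  if (design$misclassification > 0) {
    flip <- stats::runif(design$n_f2) < design$misclassification
    pheno <- xor(pheno, flip)
  }
  mut_class <- which(pheno)
  az_class <- which(!pheno)
  if (length(mut_class) < design$pool_mutant)
    stop("mutant phenotype class (", length(mut_class),
         ") smaller than the mutant pool (", design$pool_mutant, ")",
         call. = FALSE)
  if (length(az_class) < design$pool_azygous)
    stop("azygous class smaller than the azygous pool", call. = FALSE)
  mut_ids <- sample(mut_class, design$pool_mutant)
  az_ids <- sample(az_class, design$pool_azygous)
  mut_af <- colSums(cross$genotypes[mut_ids, , drop = FALSE]) /
    (2 * design$pool_mutant)
  az_af <- colSums(cross$genotypes[az_ids, , drop = FALSE]) /
    (2 * design$pool_azygous)
  wt_af <- rep(0, n_mark)

  sample_pool <- function(af) {
    depth <- stats::rpois(n_mark, design$depth_mean)
    alt <- stats::rbinom(n_mark, depth, af)
    gq <- pmin(99, round(4.3 * depth))
    list(depth = depth, alt = alt, gq = gq)
  }
  wt <- sample_pool(wt_af)
  az <- sample_pool(az_af)
  mut <- sample_pool(mut_af)
  ra <- draw_ref_alt(n_mark)
  variants <- pooled_variants(chrom = design$chrom, pos = cross$pos,
                              ref = ra$ref, alt = ra$alt,
                              wt_depth = wt$depth, wt_alt = wt$alt,
                              wt_gq = wt$gq,
                              az_depth = az$depth, az_alt = az$alt,
                              az_gq = az$gq,
                              mut_depth = mut$depth, mut_alt = mut$alt,
                              mut_gq = mut$gq)
  truth <- list(pos = cross$pos, causal_index = cross$causal_index,
                causal_pos = design$causal_pos,
                true_af = data.frame(pos = cross$pos, wt = wt_af,
                                     az = az_af, mut = mut_af),
                genotypes = cross$genotypes, phenotype = cross$phenotype)
  list(variants = variants, truth = truth)
}
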