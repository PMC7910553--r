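test_that("gas-exchange simulation is exact without noise and deterministic under seeds", {
  p <- c4_parameters()
  quiet <- simulate_gas_exchange(p, noise = noise_model(a_sd = 0), seed = 3)[[1]]
  truth <- attr(quiet, "truth")
  expect_equal(quiet$a_net, truth$a_net)
  a <- simulate_gas_exchange(p, seed = 7)[[1]]
  b <- simulate_gas_exchange(p, seed = 7)[[1]]
  expect_identical(a$a_net, b$a_net)
  c <- simulate_gas_exchange(p, seed = 8)[[1]]
  expect_false(identical(a$a_net, c$a_net))
})

test_that("replicate means concentrate on the forward model", {
  p <- c4_parameters()
  sd <- 0.5; n <- 40
  reps <- simulate_gas_exchange(p, grid = c(50, 200, 600),
                                noise = noise_model(a_sd = sd),
                                n_replicates = n, seed = 12)
  truth <- attr(reps[[1]], "truth")$a_net
  mean_a <- rowMeans(vapply(reps, function(cv) cv$a_net, numeric(3)))
  expect_true(all(abs(mean_a - truth) < 3 * sd / sqrt(n)))
})

test_that("DCDP-fed simulation sits below the uninhibited curve and recovers gbs", {
  p <- c4_parameters(gbs = 0.0028)
  grid <- c(0, 50, 75, 100, 200, 300, 400)
  dcdp <- simulate_dcdp_curve(p, grid = grid, noise = noise_model(a_sd = 0))
  full <- aci_curve(p, grid, irradiance = 1500)
  expect_true(all(dcdp$a_net[grid > 0] < full$a_net[grid > 0]))
  # at zero CO2 with the C4 cycle off the leaf respires, partially offset
  # by bundle-sheath Rubisco refixing respiratory CO2; the pure -rd limit
  # needs Rubisco absent as well
  expect_gt(dcdp$a_net[1], -p$rd)
  expect_lt(dcdp$a_net[1], 0)
  no_rub <- simulate_dcdp_curve(c4_parameters(vcmax = 0, gbs = 0.0028),
                                grid = c(0, 25, 50),
                                noise = noise_model(a_sd = 0))
  expect_equal(no_rub$a_net[1], -1, tolerance = 1e-9)
  est <- estimate_gbs_initial_slope(dcdp)$slope
  expect_lt(abs(est / 2.8 - 1), 0.25)
  # the leakier genotype has the steeper inhibited initial slope
  dcdp_mut <- simulate_dcdp_curve(c4_parameters(gbs = 0.0074), grid = grid,
                                  noise = noise_model(a_sd = 0))
  expect_gt(estimate_gbs_initial_slope(dcdp_mut)$slope, est)
})

test_that("discrimination simulation is exact without noise and recovers phi", {
  obs <- simulate_discrimination(0.29, ci_over_ca = c(0.3, 0.4, 0.5),
                                 noise = noise_model(delta_sd = 0), seed = 1)
  expect_equal(obs$delta,
               discrimination_from_leakiness(0.29, c(0.3, 0.4, 0.5)))
  a <- simulate_discrimination(0.29, rep(0.41, 8), seed = 4)
  b <- simulate_discrimination(0.29, rep(0.41, 8), seed = 4)
  expect_identical(a$delta, b$delta)
})

test_that("the simulated cross segregates 1:2:1 and pools condition on phenotype", {
  d <- cross_design()
  sim <- simulate_bc1f2_pools(d, seed = 2)
  tr <- sim$truth
  # conditioning on the recessive phenotype fixes the causal allele
  expect_equal(tr$true_af$mut[tr$causal_index], 1.0)
  expect_equal(sim$variants$mut_af[sim$variants$pos == tr$causal_pos], 1.0)
  # phenotype fraction near the monohybrid 25%
  expect_gt(mean(tr$phenotype), 0.15)
  expect_lt(mean(tr$phenotype), 0.35)
  # the wildtype pool never carries induced alleles
  expect_true(all(sim$variants$wt_alt == 0))
  # determinism
  sim2 <- simulate_bc1f2_pools(d, seed = 2)
  expect_identical(as.data.frame(sim2$variants), as.data.frame(sim$variants))
})

test_that("azygous-pool frequency at the causal site approaches 1/3 in large designs", {
  d <- cross_design(n_f2 = 500, pool_mutant = 100, pool_azygous = 300,
                    depth_mean = 100)
  az <- vapply(1:20, function(s) {
    sim <- simulate_bc1f2_pools(d, seed = s)
    sim$truth$true_af$az[sim$truth$causal_index]
  }, numeric(1))
  expect_lt(abs(mean(az) - 1 / 3), 0.05)
})

test_that("unlinked-site mutant-pool frequencies average one half", {
  # loci far from the causal site on a long, loosely linked chromosome
  d <- cross_design(n_f2 = 300, pool_mutant = 45, chrom_bp = 500e6,
                    chrom_cm = 1500, causal_pos = 250e6, depth_mean = 100,
                    n_induced = 80)
  means <- vapply(1:20, function(s) {
    sim <- simulate_bc1f2_pools(d, seed = s)
    tr <- sim$truth
    far <- abs(tr$pos - d$causal_pos) / d$chrom_bp * d$chrom_cm > 100
    mean(tr$true_af$mut[far])
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.5), 0.05)
})

test_that("pool sizes exceeding a phenotype class raise an error", {
  d <- cross_design(n_f2 = 40, pool_mutant = 30)
  expect_error(simulate_bc1f2_pools(d, seed = 1), "smaller than")
})

test_that("the causal variant survives the default filter cascade", {
  keep <- vapply(1:20, function(s) {
    sim <- simulate_bc1f2_pools(cross_design(depth_mean = 50), seed = s)
    res <- filter_variants(sim$variants)
    sim$truth$causal_pos %in% res$candidates$pos
  }, logical(1))
  expect_gte(mean(keep), 0.95)
})

test_that("simulated pools round-trip through VCF with counts preserved", {
  sim <- simulate_bc1f2_pools(cross_design(n_induced = 25), seed = 9)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_pool_vcf(sim$variants, path, contig_length = 50e6)
  back <- read_pool_vcf(path)
  orig <- as.data.frame(sim$variants)
  expect_equal(as.data.frame(back), orig[order(orig$pos), ],
               ignore_attr = TRUE)
})
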