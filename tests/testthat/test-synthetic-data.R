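# The synthetic-data generators: cohort (mixture expression + survival),
# peak samples + blacklist, negative-binomial fragment counts, motif
# membership, and gene models.

test_that("cohort simulation is reproducible and honors censoring_rate = 0", {
  cfg <- cohort_config(n_patients = 50, n_null_genes = 5, n_planted_genes = 3,
                       censoring_rate = 0, seed = 7)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$expr, s2$cohort$expr)
  expect_identical(s1$cohort$survival, s2$cohort$survival)
  expect_true(all(s1$cohort$survival$event == 1L))
  expect_identical(dim(s1$cohort$expr), c(8L, 50L))
  expect_identical(s1$truth$class, rep(c("planted", "null"), c(3, 5)))
})

test_that("planted gene means match the closed-form mixture mean", {
  cfg <- cohort_config(n_patients = 200, n_null_genes = 0,
                       n_planted_genes = 3,
                       planted_component_means = c(0.2, 3.0),
                       planted_component_sds = c(0.4, 0.4),
                       planted_mixing_weights = c(0.5, 0.5), seed = 11)
  sim <- simulate_cohort(cfg)
  mix_mean <- 0.5 * 0.2 + 0.5 * 3.0
  mix_var <- 0.5 * (0.4^2 + 0.2^2) + 0.5 * (0.4^2 + 3.0^2) - mix_mean^2
  se <- sqrt(mix_var / 200)
  for (g in 1:3) {
    expect_lt(abs(mean(sim$cohort$expr[g, ]) - mix_mean), 3 * se)
  }
})

test_that("survival obeys proportional hazards by construction", {
  cfg <- cohort_config(n_patients = 4000, n_null_genes = 0,
                       n_planted_genes = 1, hazard_ratio_per_group = 3,
                       censoring_rate = 0, seed = 5)
  sim <- simulate_cohort(cfg)
  z <- sim$patient_groups
  sv <- sim$cohort$survival
  # exponential MLE hazard per group: events / total follow-up
  h1 <- sum(sv$event[z == 1]) / sum(sv$time[z == 1])
  h2 <- sum(sv$event[z == 2]) / sum(sv$time[z == 2])
  expect_lt(abs(h2 / h1 - 3), 0.3) # within 10% of the stated ratio
})

test_that("hazard_ratio 1 decouples survival from grouping; censoring near target", {
  cfg <- cohort_config(n_patients = 2000, n_null_genes = 0,
                       n_planted_genes = 1, hazard_ratio_per_group = 1,
                       censoring_rate = 0.3, seed = 19)
  sim <- simulate_cohort(cfg)
  expect_lt(abs(mean(sim$cohort$survival$event == 0) - 0.3), 0.1)
  lr <- logrank_test(sim$cohort$survival$time, sim$cohort$survival$event,
                     sim$patient_groups)
  expect_gt(lr$p, 0.001) # null: no association with the latent groups
})

test_that("cohort config validation", {
  expect_error(cohort_config(planted_mixing_weights = c(0.6, 0.6)), "sum to 1")
  expect_error(cohort_config(planted_component_sds = c(0.5, -1)), "positive")
  expect_error(cohort_config(hazard_ratio_per_group = 0), "positive")
  expect_error(cohort_config(censoring_rate = 1), "censoring_rate")
  expect_error(cohort_config(n_null_genes = 0, n_planted_genes = 0),
               "at least one gene")
})

test_that("peak sample simulation: blacklist, determinism, shared archetypes", {
  g <- toy_genome()
  sim0 <- simulate_peak_samples(g, blacklist_fraction = 0, seed = 2)
  expect_identical(nrow(sim0$blacklist), 0L)

  a <- simulate_peak_samples(g, seed = 3)
  b <- simulate_peak_samples(g, seed = 3)
  expect_identical(a$samples, b$samples)
  expect_identical(a$blacklist, b$blacklist)

  # identical per-sample seeds -> identical summit sets
  tw <- simulate_peak_samples(g, n_samples = 2, seed = 4,
                              sample_seeds = c(77, 77))
  expect_identical(tw$samples[[1]], tw$samples[[2]])

  # archetype design guarantees cross-sample overlap after standardization
  sim <- simulate_peak_samples(g, n_samples = 3, peaks_per_sample = 30,
                               seed = 5)
  std <- lapply(sim$samples, standardize_peaks, genome = g)
  cross <- bf_overlaps_any(std[[1]], std[[2]])
  expect_gt(sum(cross), 0)
  # deliberately planted blacklist and chrY summits are present
  expect_true(any(bf_overlaps_any(std[[1]], sim$blacklist)))
  expect_true(any(std[[1]]$chrom == "chrY"))
  expect_error(simulate_peak_samples(toy_genome(c(chr1 = 100)), seed = 1),
               "too short")
})

test_that("fragment count simulation has the planted NB structure", {
  cons <- sprintf("peak_%03d", 1:200)
  design <- c(a1 = "ctrl", a2 = "ctrl", a3 = "ctrl", a4 = "ctrl", a5 = "ctrl",
              b1 = "kd", b2 = "kd", b3 = "kd", b4 = "kd", b5 = "kd")
  lfc <- c(peak_001 = 2)
  cm <- simulate_fragment_counts(cons, design, planted_lfc = lfc,
                                 dispersion = 0.05, lib_sizes = rep(1e6, 10),
                                 seed = 8)
  expect_s3_class(cm, "count_matrix")
  expect_identical(attr(cm, "truth")[["peak_001"]], 2)
  ratio <- mean(cm$counts["peak_001", 6:10]) / mean(cm$counts["peak_001", 1:5])
  expect_lt(abs(log2(ratio) - 2), 0.5)
  # unplanted peak: conditions share expected counts
  r0 <- mean(cm$counts["peak_002", 6:10]) / mean(cm$counts["peak_002", 1:5])
  expect_lt(abs(log2(r0)), 0.5)

  # doubling one library size roughly doubles its column sum
  cm2 <- simulate_fragment_counts(cons, design[1:2], dispersion = 0.05,
                                  lib_sizes = c(1e5, 2e5), seed = 9)
  expect_lt(abs(sum(cm2$counts[, 2]) / sum(cm2$counts[, 1]) - 2), 0.3)
  expect_error(simulate_fragment_counts(cons, design, dispersion = 0),
               "dispersion")
  expect_error(simulate_fragment_counts(character(0), design), "empty")
})

test_that("motif membership density, planting, and guarantees", {
  cons <- sprintf("peak_%03d", 1:300)
  mm <- simulate_motif_matches(cons, n_motifs = 40, match_prob = 0.15,
                               seed = 4)
  expect_identical(dim(mm$matches), c(40L, 300L))
  # density within a 4-sigma binomial band around match_prob
  n_cells <- length(mm$matches)
  band <- 4 * sqrt(0.15 * 0.85 / n_cells)
  expect_lt(abs(mean(mm$matches) - 0.15), band + 1e-9)
  expect_true(all(rowSums(mm$matches) >= 1))
  expect_true(all(mm$gc >= 0 & mm$gc <= 1))

  # near-1 probability saturates membership
  mm1 <- simulate_motif_matches(cons, n_motifs = 5, match_prob = 0.99,
                                seed = 5)
  expect_gt(mean(mm1$matches), 0.97)

  # planted motifs preferentially hit the planted peaks
  mm2 <- simulate_motif_matches(cons, n_motifs = 20, match_prob = 0.1,
                                planted_condition_motifs = 2,
                                planted_peaks = 1:50,
                                planted_match_prob = 0.8, seed = 6)
  expect_gt(mean(mm2$matches[1, 1:50]), mean(mm2$matches[1, 51:300]))
  expect_error(simulate_motif_matches(cons, n_motifs = 0), "n_motifs")
  expect_error(simulate_motif_matches(cons, match_prob = 1), "match_prob")
})

test_that("gene model simulation places valid stranded TSS", {
  g <- toy_genome()
  tss <- simulate_gene_models(g, n_genes = 400, seed = 3)
  expect_identical(nrow(tss), 400L)
  expect_false(anyDuplicated(tss$gene) > 0)
  expect_true(all(tss$tss >= 0 & tss$tss < as.numeric(g[tss$chrom])))
  # strands ~50/50 within a 4-sigma binomial band
  expect_lt(abs(mean(tss$strand == "+") - 0.5), 4 * sqrt(0.25 / 400))
  # sorted within chromosome
  expect_false(is.unsorted(tss$tss[tss$chrom == "chr1"]))
  one <- simulate_gene_models(g, n_genes = 1, seed = 1)
  expect_identical(nrow(one), 1L)
  expect_error(simulate_gene_models(toy_genome(c(chr1 = 50)), n_genes = 10),
               "too small")
})
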