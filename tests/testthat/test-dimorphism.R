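test_that("de_test computes exact fold-changes and null behaviour", {
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    animal_id = paste0("a", 1:6),
    organ = "liver",
    sex = rep(c("male", "female"), each = 3),
    group = "CA")
  expr <- rbind(
    doubling = c(1023, 1023, 1023, 2047, 2047, 2047),
    flat = rep(7, 6))
  colnames(expr) <- meta$sample_id
  de <- de_test(expr, meta, sex == "male", sex == "female")
  expect_equal(de$log2fc[de$gene == "doubling"], 1)   # log2(2048/1024)
  expect_equal(de$log2fc[de$gene == "flat"], 0)
  expect_equal(de$p[de$gene == "flat"], 1)
  expect_error(de_test(expr, meta, group == "XX", sex == "male"),
               "no samples", class = "interorgan_error")
  expect_true(all(de$padj >= de$p - 1e-15))
})

test_that("BH adjustment matches the step-up definition on a hand-checked case", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03))
})

test_that("sex-bias classes follow strict thresholds and partition genes", {
  de <- tibble::tibble(gene = paste0("g", 1:4),
                       log2fc = c(1.5, 1.5, -1.0, -2),
                       p = c(0.001, 0.1, 0.0005, 0.001),
                       padj = c(0.01, 0.2, 0.001, 0.004))
  bias <- classify_sex_bias(de)
  expect_identical(bias$bias, c("male_biased", "unbiased", "unbiased", "female_biased"))
  expect_true(all(table(bias$bias) >= 0))  # partition is exhaustive by construction
  expect_equal(sum(bias$bias %in% c("male_biased", "female_biased", "unbiased")), 4L)
})

test_that("planted sex-biased genes are recovered with controlled FDR", {
  sens <- c(); fdr <- c()
  for (seed in c(21, 22, 23)) {
    sim <- small_sim(seed = seed)
    de <- de_test_samples(sim$expr,
                          pick(sim$design, "liver", "CA", "female"),
                          pick(sim$design, "liver", "CA", "male"))
    bias <- classify_sex_bias(de)
    truth_m <- sim$truth$male_biased; truth_f <- sim$truth$female_biased
    tp <- sum(bias$gene[bias$bias == "male_biased"] %in% truth_m) +
      sum(bias$gene[bias$bias == "female_biased"] %in% truth_f)
    called <- sum(bias$bias != "unbiased")
    sens <- c(sens, tp / (length(truth_m) + length(truth_f)))
    fdr <- c(fdr, (called - tp) / max(called, 1))
  }
  expect_true(all(sens >= 0.9))
  expect_true(all(fdr <= 0.05))
})

test_that("DEG grid shows attenuation in warm-acclimated animals", {
  sim <- small_sim(seed = 31, attenuation_fraction = 1)
  suppressWarnings(grid <- deg_count_grid(sim$expr, sim$design))
  expect_equal(nrow(grid), 28L)
  ca <- grid$n_deg[grid$group == "CA"]
  wa <- grid$n_deg[grid$group == "WA"]
  expect_true(all(wa < ca))  # full attenuation removes WA dimorphism
  # single-organ input gives a 1x4 grid
  liver_meta <- sim$design[sim$design$organ == "liver", ]
  liver_expr <- sim$expr[, liver_meta$sample_id]
  g1 <- deg_count_grid(liver_expr, liver_meta)
  expect_equal(dim(g1), c(4L, 3L))
})

test_that("attenuation analysis reports the expected mirrored sign pattern", {
  sim <- small_sim(seed = 41)
  de_ca <- de_test_samples(sim$expr,
                           pick(sim$design, "liver", "CA", "female"),
                           pick(sim$design, "liver", "CA", "male"))
  bias <- classify_sex_bias(de_ca)
  de_m <- de_test_samples(sim$expr, pick(sim$design, "liver", "CA", "male"),
                          pick(sim$design, "liver", "WA", "male"))
  de_f <- de_test_samples(sim$expr, pick(sim$design, "liver", "CA", "female"),
                          pick(sim$design, "liver", "WA", "female"))
  at <- attenuation_analysis(bias, de_m, de_f)
  expect_equal(nrow(at), 4L)
  expect_true(all(at$frac_expected_sign > 0.5))
  expect_true(all(at$sign_test_p < 0.05))
  # males lose male-biased expression, gain female-biased; mirrored in females
  expect_lt(at$median_log2fc[at$sex == "male" & at$bias == "male_biased"], 0)
  expect_gt(at$median_log2fc[at$sex == "male" & at$bias == "female_biased"], 0)
  expect_gt(at$median_log2fc[at$sex == "female" & at$bias == "male_biased"], 0)
  expect_lt(at$median_log2fc[at$sex == "female" & at$bias == "female_biased"], 0)
})

test_that("attenuation handles degenerate inputs", {
  bias <- tibble::tibble(gene = "g1", log2fc = 2, p = 0.001, padj = 0.01,
                         bias = "male_biased")
  de1 <- tibble::tibble(gene = "g1", log2fc = -0.4, p = 0.5, padj = 0.5)
  at <- attenuation_analysis(bias, de1, de1)
  male_cell <- at[at$sex == "male" & at$bias == "male_biased", ]
  expect_equal(male_cell$frac_expected_sign, 1)
  expect_equal(male_cell$sign_test_p, 1)      # two-sided sign test, n = 1
  empty_cell <- at[at$sex == "male" & at$bias == "female_biased", ]
  expect_equal(empty_cell$n_genes, 0L)
  expect_true(is.na(empty_cell$sign_test_p))
})

test_that("increasing attenuation strengthens the expected-sign fraction", {
  fracs <- vapply(c(0, 0.5, 1), function(af) {
    out <- numeric(0)
    for (seed in 1:8) {
      sim <- small_sim(seed = 300 + seed, n_genes = 400, n_secreted = 5,
                       n_targets = 0, n_male_biased = 40, n_female_biased = 40,
                       n_temp_genes = 0, attenuation_fraction = af,
                       regulator_r = 0)
      de_ca <- de_test_samples(sim$expr,
                               pick(sim$design, "liver", "CA", "female"),
                               pick(sim$design, "liver", "CA", "male"))
      bias <- classify_sex_bias(de_ca)
      de_m <- de_test_samples(sim$expr, pick(sim$design, "liver", "CA", "male"),
                              pick(sim$design, "liver", "WA", "male"))
      de_f <- de_test_samples(sim$expr, pick(sim$design, "liver", "CA", "female"),
                              pick(sim$design, "liver", "WA", "female"))
      at <- attenuation_analysis(bias, de_m, de_f)
      out <- c(out, mean(at$frac_expected_sign, na.rm = TRUE))
    }
    mean(out)
  }, numeric(1))
  expect_gte(fracs[2] + 0.05, fracs[1])
  expect_gte(fracs[3] + 0.05, fracs[2])
  expect_gt(fracs[3], fracs[1])
})
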