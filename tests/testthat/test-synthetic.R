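test_that("design generator reproduces the reciprocal-transfer layout", {
  d <- sim_design(sim_config())
  expect_equal(nrow(d), 168L)
  expect_equal(length(unique(d$animal_id)), 24L)
  cs <- d[!duplicated(d$animal_id) & d$group == "CS", ]
  expect_equal(sum(cs$sex == "male"), 4L)
  expect_equal(sum(cs$sex == "female"), 2L)
  # minimal design
  tiny <- sim_config(organs = "liver", animals_per_group = 1,
                     sex_split = list(CA = c(1, 0), CS = c(1, 0),
                                      WS = c(0, 1), WA = c(0, 1)),
                     n_genes = 10, n_secreted = 1, n_targets = 1,
                     n_male_biased = 1, n_female_biased = 1, n_temp_genes = 1,
                     origin_organ = "liver", target_organ = "liver")
  expect_equal(nrow(sim_design(tiny)), 4L)
  expect_error(sim_config(animals_per_group = 6,
                          sex_split = list(CA = c(3, 3), CS = c(2, 2),
                                           WS = c(3, 3), WA = c(3, 3))),
               "inconsistent", class = "interorgan_error")
})

test_that("generation is deterministic given config and seed", {
  cfg <- sim_config(seed = 13, n_genes = 100, n_secreted = 5, n_targets = 10,
                    n_male_biased = 5, n_female_biased = 5, n_temp_genes = 5)
  d <- sim_design(cfg)
  s1 <- sim_expression(d, cfg)
  s2 <- sim_expression(d, cfg)
  expect_identical(s1, s2)
  i1 <- sim_intron_fixtures(cfg)
  expect_identical(i1, sim_intron_fixtures(cfg))
  s3 <- sim_expression(d, sim_config(seed = 14, n_genes = 100, n_secreted = 5,
                                     n_targets = 10, n_male_biased = 5,
                                     n_female_biased = 5, n_temp_genes = 5))
  expect_false(identical(s1$expr, s3$expr))
})

test_that("organ identity dominates expression variance", {
  sim <- small_sim(seed = 2, n_genes = 300, n_secreted = 5, n_targets = 20,
                   n_male_biased = 10, n_female_biased = 10, n_temp_genes = 10)
  lx <- log2(sim$expr + 1)
  organ <- sim$design$organ[match(colnames(lx), sim$design$sample_id)]
  frac <- vapply(seq_len(nrow(lx)), function(i) {
    v <- lx[i, ]
    fit <- tapply(v, organ, mean)[organ]
    1 - sum((v - fit)^2) / sum((v - mean(v))^2)
  }, numeric(1))
  expect_gt(mean(frac), 0.5)
})

test_that("null sex effect produces near-zero fold changes on 'biased' genes", {
  sim <- small_sim(seed = 4, n_genes = 300, n_secreted = 5, n_targets = 20,
                   n_male_biased = 20, n_female_biased = 20, n_temp_genes = 0,
                   sex_effect = 0)
  de <- de_test_samples(sim$expr,
                        pick(sim$design, "liver", "CA", "female"),
                        pick(sim$design, "liver", "CA", "male"))
  fc <- de$log2fc[de$gene %in% c(sim$truth$male_biased, sim$truth$female_biased)]
  se <- sd(fc) / sqrt(length(fc))
  expect_lt(abs(mean(fc)), 3 * se + 1e-8)
})

test_that("planted cross-organ correlation is achieved at the configured level", {
  sim <- small_sim(seed = 6, n_genes = 500, n_secreted = 5, n_targets = 50,
                   n_male_biased = 0, n_female_biased = 0, n_temp_genes = 0)
  paired <- pair_by_animal(sim$expr, sim$design, "liver", "small_intestine")
  reg <- log2(paired$origin[sim$truth$regulator, ])
  target_mean <- colMeans(log2(paired$target[sim$truth$targets, ]))
  r <- bicor(reg, target_mean)$r
  # single-gene planted r = 0.7 at n = 24; the mean over targets is less
  # noisy, so r must fall in the Fisher-z band around 0.7 or above it
  expect_gt(r, 0.45)
  per_gene <- vapply(sim$truth$targets[1:20], function(g) {
    bicor(reg, log2(paired$target[g, ]))$r
  }, numeric(1))
  expect_lt(abs(mean(per_gene) - 0.7), 0.25)
})

test_that("intron fixtures cover pass, single-failure and boundary cases", {
  fx <- sim_intron_fixtures(sim_config(seed = 9))
  recs <- score_introns(fx$introns, fx$depth, fx$junctions)
  # each threshold is the sole failing criterion for at least one fixture
  fr <- recs[recs$intron_id == "fail_ratio_only", ]
  expect_true(fr$ir_ratio <= 0.5 && fr$coverage > 0.9 && fr$intron_depth > 1)
  fc <- recs[recs$intron_id == "fail_cov_only", ]
  expect_true(fc$ir_ratio > 0.5 && fc$coverage <= 0.9 && fc$intron_depth > 1)
  fd <- recs[recs$intron_id == "fail_depth_only", ]
  expect_true(fd$ir_ratio > 0.5 && fd$coverage > 0.9 && fd$intron_depth <= 1)
  # boundary fixtures sit exactly at the thresholds
  expect_equal(recs$ir_ratio[recs$intron_id == "bnd_ratio"], 0.5)
  expect_equal(recs$coverage[recs$intron_id == "bnd_cov"], 0.9)
  expect_equal(recs$intron_depth[recs$intron_id == "bnd_depth"], 1)
  expect_setequal(filter_introns(recs)$intron_id, fx$truth)
})

test_that("all-null simulation shows no significant structure at nominal rates", {
  # sex-bias false calls and bicor screen hits under a fully null generator
  fp_bias <- 0; n_pairs <- 0; n_sig <- 0
  for (seed in 1:20) {
    sim <- small_sim(seed = seed, n_genes = 120, n_secreted = 4, n_targets = 0,
                     n_male_biased = 10, n_female_biased = 10, n_temp_genes = 0,
                     sex_effect = 0, temp_effect = 0, regulator_r = 0)
    de <- de_test_samples(sim$expr,
                          pick(sim$design, "liver", "CA", "female"),
                          pick(sim$design, "liver", "CA", "male"))
    fp_bias <- fp_bias + sum(classify_sex_bias(de)$bias != "unbiased")
    paired <- pair_by_animal(sim$expr, sim$design, "liver", "small_intestine")
    sc <- bicor_screen(paired$origin[sim$truth$secreted, ], paired$target)
    n_sig <- n_sig + sum(sc$p < 0.05)
    n_pairs <- n_pairs + length(sc$p)
  }
  expect_lt(fp_bias / (20 * 120), 0.01)          # BH keeps false calls rare
  expect_lt(abs(n_sig / n_pairs - 0.05), 0.015)  # raw p calibrated near nominal
})
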