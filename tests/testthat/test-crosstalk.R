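test_that("significance score is the sum of -log10 p", {
  expect_equal(significance_score(c(0.1, 0.01, 1)), 3)
  expect_equal(significance_score(rep(1, 10)), 0)
  p <- c(0.2, 0.04, 0.5)
  base <- significance_score(p)
  p2 <- p; p2[2] <- p2[2] / 2
  expect_equal(significance_score(p2) - base, log10(2))
  expect_error(significance_score(numeric(0)), "empty", class = "interorgan_error")
  # additivity over concatenated rows
  a <- runif(5); b <- runif(7)
  expect_equal(significance_score(c(a, b)),
               significance_score(a) + significance_score(b))
  # floor keeps the score finite
  expect_true(is.finite(significance_score(c(0, 1e-320))))
})

test_that("specificity filter demands a strict origin-organ maximum", {
  design <- sim_design(sim_config(n_genes = 10, n_secreted = 1, n_targets = 1,
                                  n_male_biased = 1, n_female_biased = 1,
                                  n_temp_genes = 1))
  ns <- nrow(design)
  expr <- matrix(1, nrow = 2, ncol = ns,
                 dimnames = list(c("hi_liver", "flat"), design$sample_id))
  expr["hi_liver", design$organ == "liver"] <- 100
  pass <- specificity_filter(c("hi_liver", "flat"), expr, design, "liver")
  expect_true(pass[["hi_liver"]])
  expect_false(pass[["flat"]])   # exact tie across organs fails (strict)
  expect_error(specificity_filter("hi_liver", expr[, design$organ != "liver"],
                                  design, "liver"),
               "zero samples", class = "interorgan_error")
})

test_that("specificity filter removes organ-uniform genes", {
  # genes whose per-organ means coincide can never show a strict maximum
  removed <- 0; total <- 0
  for (seed in 1:5) {
    design <- sim_design(sim_config(seed = seed))
    ns <- nrow(design)
    genes <- paste0("u", 1:20)
    expr <- matrix(rep(seq(1, 20), ns), nrow = 20,
                   dimnames = list(genes, design$sample_id))
    pass <- specificity_filter(genes, expr, design, "liver")
    removed <- removed + sum(!pass); total <- total + length(pass)
  }
  expect_gte(removed / total, 0.99)
})

test_that("regulator ranking recovers the planted secreted gene", {
  sim <- small_sim(seed = 8)
  ct <- rank_regulators(sim$expr, sim$design, sim$truth$secreted)
  expect_identical(ct$scores$secreted_gene[1], sim$truth$regulator)
  expect_true(ct$scores$passed_specificity[1])
  expect_identical(ct$scores$rank, seq_len(nrow(ct$scores)))
  # selected targets obey both strict thresholds
  expect_true(all(ct$targets$r > 0.5 & ct$targets$p < 0.05))
  top_targets <- ct$targets$target_gene[ct$targets$secreted_gene == sim$truth$regulator]
  expect_gt(mean(top_targets %in% sim$truth$targets), 0.9)
})

test_that("ranks are stable under input permutation and ties break by id", {
  sim <- small_sim(seed = 12, n_genes = 300, n_secreted = 10, n_targets = 30,
                   n_male_biased = 0, n_female_biased = 0, n_temp_genes = 0)
  ct1 <- rank_regulators(sim$expr, sim$design, sim$truth$secreted)
  perm <- sample(nrow(sim$expr))
  ct2 <- rank_regulators(sim$expr[perm, ], sim$design, rev(sim$truth$secreted))
  expect_identical(ct1$scores$secreted_gene, ct2$scores$secreted_gene)
  expect_equal(ct1$scores$score, ct2$scores$score, tolerance = 1e-12)
})

test_that("single secreted gene input ranks first trivially", {
  sim <- small_sim(seed = 3, n_genes = 100, n_secreted = 1, n_targets = 10,
                   n_male_biased = 0, n_female_biased = 0, n_temp_genes = 0)
  ct <- rank_regulators(sim$expr, sim$design, sim$truth$regulator)
  expect_equal(nrow(ct$scores), 1L)
  expect_equal(ct$scores$rank, 1L)
  expect_error(rank_regulators(sim$expr, sim$design, "not_a_gene"),
               "no secreted gene", class = "interorgan_error")
})

test_that("recovery power rises with planted correlation and target count", {
  grid <- tidyr::expand_grid(r = c(0.3, 0.5, 0.7), nt = c(10, 30, 60))
  rec <- purrr::pmap_dbl(grid, function(r, nt) {
    hits <- 0
    for (seed in 1:20) {
      sim <- small_sim(seed = 1000 + seed, n_genes = 300, n_secreted = 10,
                       n_targets = nt, regulator_r = r,
                       n_male_biased = 0, n_female_biased = 0, n_temp_genes = 0)
      ct <- rank_regulators(sim$expr, sim$design, sim$truth$secreted)
      hits <- hits + (ct$scores$secreted_gene[1] == sim$truth$regulator)
    }
    hits / 20
  })
  m <- matrix(rec, 3, 3, byrow = TRUE)  # rows: r, cols: nt
  # strongest corner beats weakest corner, and monotone along both edges
  expect_gte(m[3, 3], m[1, 1])
  expect_gte(m[3, 1] + 0.1, m[1, 1])
  expect_gte(m[1, 3] + 0.1, m[1, 1])
  expect_gte(m[3, 3] + 0.1, max(m[1, 3], m[3, 1]))
})

test_that("enrich_targets tests the top regulator's targets against the screen universe", {
  sim <- small_sim(seed = 8)
  ct <- rank_regulators(sim$expr, sim$design, sim$truth$secreted)
  sets <- list(
    planted = list(term_name = "planted targets", genes = sim$truth$targets),
    random = list(term_name = "unrelated", genes = paste0("g", sprintf("%04d", 1901:1950)))
  )
  en <- enrich_targets(ct, sets)
  expect_lt(en$p[en$term == "planted"], 1e-10)
  expect_gt(en$p[en$term == "random"], 0.05)
  # empty targets warn, not error
  ct$targets <- ct$targets[0, ]
  expect_warning(res <- enrich_targets(ct, sets), "empty")
  expect_equal(nrow(res), 0L)
})
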