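#' Simulation configuration for the reciprocal-transfer design
#'
#' Builds the configuration consumed by [sim_design()], [sim_expression()]
#' and [sim_intron_fixtures()]. Defaults emulate the study design the
#' package targets: 4 temperature groups (CA cool-acclimated, CS
#' cool-switched, WS warm-switched, WA warm-acclimated), 6 animals per
#' group with a 3:3 male:female split except CS at 4:2, and 7 organs per
#' animal (168 samples from 24 animals).
#'
#' Expression is log-normal: gaussian on the log2 scale with additive
#' effects, then exponentiated to FPKM. The organ main effect dominates
#' total variance; sex effects apply to designated biased genes; a
#' temperature effect applies to responsive genes at full strength in WA,
#' at `switch_fraction` of full strength in the switched groups, and not at
#' all in CA; a planted liver-secreted regulator shares a latent
#' animal-level factor with its target genes in a distal organ, which
#' induces a controlled cross-organ correlation.
#'
#' Default effect sizes are fixed by a-priori power analysis of the 3-vs-3
#' within-group contrast (see the methods vignette), not fitted to data.
#'
#' @param n_genes Number of genes.
#' @param n_secreted Number of secreted-protein genes (first gene block);
#'   all receive an origin-organ expression offset so they are
#'   liver-primary.
#' @param animals_per_group Animals in each of the four groups.
#' @param sex_split Named list group -> c(male, female) counts.
#' @param organs Organ vector.
#' @param regulator_r Planted cross-organ correlation between the regulator
#'   and each of its targets, in (-1, 1).
#' @param n_targets Number of planted target genes in the target organ.
#' @param origin_organ,target_organ Organs for the planted regulator.
#' @param n_male_biased,n_female_biased Planted sex-biased gene counts.
#' @param sex_effect Sex effect size, log2 units (full male-female
#'   difference in CA).
#' @param n_temp_genes Temperature-responsive gene count.
#' @param temp_effect Temperature effect size, log2 units (WA vs CA).
#' @param attenuation_fraction Fraction of sex-biased genes whose
#'   dimorphism shrinks with warming.
#' @param switch_fraction Strength of temperature-linked effects in the
#'   switched groups relative to WA.
#' @param organ_effect_sd SD of per-gene organ effects, log2 units.
#' @param secreted_origin_offset Extra origin-organ log2 offset for
#'   secreted genes.
#' @param noise_sd Residual log2-scale SD.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 FPKM
#'   distribution.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_secreted = 50,
                       animals_per_group = 6,
                       sex_split = list(CA = c(3, 3), CS = c(4, 2),
                                        WS = c(3, 3), WA = c(3, 3)),
                       organs = ORGANS,
                       regulator_r = 0.7,
                       n_targets = 200,
                       origin_organ = "liver",
                       target_organ = "small_intestine",
                       n_male_biased = 100,
                       n_female_biased = 100,
                       sex_effect = 4,
                       n_temp_genes = 200,
                       temp_effect = 2,
                       attenuation_fraction = 0.8,
                       switch_fraction = 0.5,
                       organ_effect_sd = 2,
                       secreted_origin_offset = 8,
                       noise_sd = 0.25,
                       baseline_mean = 6,
                       baseline_sd = 1.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_genes, n_secreted, animals_per_group,
              n_male_biased, n_female_biased, n_temp_genes, n_targets)
  if (any(counts < 0) || n_genes < 1) abort("counts must be positive", class = "interorgan_error")
  if (abs(regulator_r) >= 1) abort("regulator_r must lie in (-1, 1)", class = "interorgan_error")
  if (attenuation_fraction < 0 || attenuation_fraction > 1) {
    abort("attenuation_fraction must lie in [0, 1]", class = "interorgan_error")
  }
  if (!all(names(sex_split) == GROUPS)) {
    abort("sex_split must name the groups CA, CS, WS, WA in order", class = "interorgan_error")
  }
  bad <- vapply(sex_split, function(x) sum(x) != animals_per_group, logical(1))
  if (any(bad)) {
    abort(paste0("sex_split inconsistent with animals_per_group for group(s): ",
                 paste(names(sex_split)[bad], collapse = ", ")), class = "interorgan_error")
  }
  if (n_secreted + n_male_biased + n_female_biased + n_temp_genes + n_targets > n_genes) {
    abort("gene role blocks exceed n_genes", class = "interorgan_error")
  }
  if (!all(c(origin_organ, target_organ) %in% organs)) {
    abort("origin/target organ not in organ list", class = "interorgan_error")
  }
  structure(cfg, class = "sim_config")
}

#' Generate design metadata
#'
#' One sample per (animal, organ). Deterministic: the design is purely
#' combinatorial.
#'
#' @param config A [sim_config()].
#' @return Sample metadata tibble (validated, see [read_metadata()]).
#' @export
sim_design <- function(config = sim_config()) {
  animals <- purrr::imap(config$sex_split, function(ns, g) {
    tibble(group = g,
           sex = rep(SEXES, times = ns),
           animal_idx = seq_len(sum(ns)))
  }) |> bind_rows()
  animals$animal_id <- sprintf("A%02d", seq_len(nrow(animals)))
  design <- tidyr::expand_grid(animals, organ = config$organs) |>
    mutate(sample_id = paste0(.data$animal_id, "_", .data$organ)) |>
    select("sample_id", "animal_id", "organ", "sex", "group")
  validate_metadata(design)
}

# Current-warmth weight of each group: drives both the temperature effect
# and the warming-linked attenuation of sex bias. Acclimated groups are at
# the extremes; switched groups sit at switch_fraction.
group_warmth <- function(groups, switch_fraction) {
  w <- c(CA = 0, CS = switch_fraction, WS = switch_fraction, WA = 1)
  unname(w[groups])
}

#' Generate an expression matrix with planted structure
#'
#' Log-normal FPKM with additive log2-scale effects (see [sim_config()]).
#' Gene roles occupy fixed, disjoint id blocks so the truth record is
#' self-describing: secreted genes first (the planted regulator is the
#' first gene), then male-biased, female-biased, temperature-responsive,
#' and crosstalk-target blocks.
#'
#' @param design Metadata from [sim_design()].
#' @param config The same [sim_config()].
#' @return List with `expr` (matrix, genes x samples) and `truth`, a list
#'   recording planted regulator/targets, biased genes, responsive genes
#'   and the secreted gene ids.
#' @export
sim_expression <- function(design, config = sim_config()) {
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("g%04d", seq_len(ng))
  idx <- gene_role_blocks(config)
  truth <- list(
    secreted = genes[idx$secreted],
    regulator = genes[idx$regulator],
    targets = genes[idx$targets],
    male_biased = genes[idx$male_biased],
    female_biased = genes[idx$female_biased],
    attenuated = character(0),
    temp_responsive = genes[idx$temp],
    origin_organ = config$origin_organ,
    target_organ = config$target_organ
  )

  ns <- nrow(design)
  baseline <- rnorm(ng, config$baseline_mean, config$baseline_sd)
  organ_eff <- matrix(rnorm(ng * length(config$organs), 0, config$organ_effect_sd),
                      nrow = ng, dimnames = list(genes, config$organs))
  organ_eff[idx$secreted, config$origin_organ] <-
    organ_eff[idx$secreted, config$origin_organ] + config$secreted_origin_offset

  # warming-linked attenuation applies to a fixed fraction of biased genes
  biased <- c(idx$male_biased, idx$female_biased)
  n_att <- round(config$attenuation_fraction * length(biased))
  attenuated <- if (n_att > 0) sort(sample(biased, n_att)) else integer(0)
  truth$attenuated <- genes[attenuated]

  warmth <- group_warmth(design$group, config$switch_fraction)
  sex_sign <- ifelse(design$sex == "male", 0.5, -0.5)

  log2expr <- matrix(baseline, ng, ns) + organ_eff[, design$organ]

  # sex effect: +s/2 in males / -s/2 in females for male-biased genes,
  # mirrored for female-biased; shrunk by warmth for attenuated genes
  if (length(biased) > 0 && config$sex_effect != 0) {
    dir <- numeric(ng)
    dir[idx$male_biased] <- 1
    dir[idx$female_biased] <- -1
    shrink <- matrix(1, ng, ns)
    if (length(attenuated) > 0) {
      shrink[attenuated, ] <- matrix(1 - warmth, length(attenuated), ns, byrow = TRUE)
    }
    log2expr <- log2expr +
      (dir * config$sex_effect) * shrink * matrix(sex_sign, ng, ns, byrow = TRUE)
  }

  if (length(idx$temp) > 0 && config$temp_effect != 0) {
    tdir <- numeric(ng)
    tdir[idx$temp] <- rep(c(1, -1), length.out = length(idx$temp))
    log2expr <- log2expr +
      (tdir * config$temp_effect) %o% warmth
  }

  # planted regulator: shared latent animal factor between the secreted
  # gene in the origin organ and each target gene in the target organ;
  # loading chosen so the expected pairwise correlation equals regulator_r
  if (length(idx$targets) > 0 && config$regulator_r != 0) {
    animals <- sort(unique(design$animal_id))
    z <- setNames(rnorm(length(animals)), animals)
    lambda <- config$noise_sd * sqrt(abs(config$regulator_r) / (1 - abs(config$regulator_r)))
    zs <- z[design$animal_id] * lambda
    in_origin <- design$organ == config$origin_organ
    in_target <- design$organ == config$target_organ
    log2expr[idx$regulator, in_origin] <- log2expr[idx$regulator, in_origin] + zs[in_origin]
    s <- sign(config$regulator_r)
    log2expr[idx$targets, in_target] <-
      log2expr[idx$targets, in_target] +
      matrix(s * zs[in_target], length(idx$targets), sum(in_target), byrow = TRUE)
  }

  log2expr <- log2expr + matrix(rnorm(ng * ns, 0, config$noise_sd), ng, ns)
  expr <- 2^log2expr
  dimnames(expr) <- list(genes, design$sample_id)
  list(expr = expr, truth = truth)
}

gene_role_blocks <- function(config) {
  stops <- cumsum(c(config$n_secreted, config$n_male_biased, config$n_female_biased,
                    config$n_temp_genes, config$n_targets))
  starts <- c(1L, head(stops, -1) + 1L)
  blk <- function(i) if (stops[i] >= starts[i]) seq(starts[i], stops[i]) else integer(0)
  list(secreted = blk(1),
       regulator = if (config$n_secreted > 0) 1L else integer(0),
       male_biased = blk(2), female_biased = blk(3),
       temp = blk(4), targets = blk(5))
}

#' Generate intron-retention fixtures with known truth
#'
#' Produces intron intervals, a per-base depth track, junction read counts
#' and the set of truly retained introns. Retained introns pass all three
#' retention thresholds (ratio > 0.5, coverage > 0.9, depth > 1); rejected
#' fixtures include, for each threshold, at least one intron failing on
#' that criterion alone, plus boundary fixtures sitting exactly at each
#' threshold (excluded under strict inequality).
#'
#' @param config A [sim_config()] (only `seed` is used).
#' @param n_retained,n_spliced Counts of truly retained and clearly spliced
#'   introns beyond the fixed single-failure and boundary fixtures.
#' @param intron_length Bases per intron.
#' @return List with tibbles `introns` (BED-style intervals), `depth`
#'   (bedGraph-style track), `junctions`, and `truth` (retained intron
#'   ids).
#' @export
sim_intron_fixtures <- function(config = sim_config(), n_retained = 5,
                                n_spliced = 5, intron_length = 100L) {
  set.seed(config$seed + 101L)
  L <- intron_length
  specs <- list()
  add <- function(specs, id, depth_val, cov_frac, junctions, retained) {
    c(specs, list(list(id = id, depth = depth_val, cov = cov_frac,
                       junc = junctions, retained = retained)))
  }
  for (i in seq_len(n_retained)) {
    d <- round(runif(1, 4, 20), 1)
    specs <- add(specs, sprintf("ret%02d", i), d, 1, max(0L, round(d * runif(1, 0, 0.6))), TRUE)
  }
  for (i in seq_len(n_spliced)) {
    d <- round(runif(1, 0.2, 0.9), 1)   # fails depth, and ratio, vs many junctions
    specs <- add(specs, sprintf("spl%02d", i), d, runif(1, 0.3, 0.7), 20L + i, FALSE)
  }
  # single-criterion failures: each threshold the sole failing criterion
  specs <- add(specs, "fail_ratio_only", 6, 1, 10L, FALSE)      # ratio 6/16 = 0.375
  specs <- add(specs, "fail_cov_only",   6, 0.8, 1L, FALSE)     # coverage 0.8
  specs <- add(specs, "fail_depth_only", 0.9, 1, 0L, FALSE)     # depth 0.9, ratio 1
  # exact-boundary fixtures, all excluded by strict inequalities
  specs <- add(specs, "bnd_ratio", 6, 1, 6L, FALSE)             # ratio exactly 0.5
  specs <- add(specs, "bnd_cov",   6, 0.9, 1L, FALSE)           # coverage exactly 0.9
  specs <- add(specs, "bnd_depth", 1, 1, 0L, FALSE)             # depth exactly 1.0

  gap <- 50L
  introns <- tibble(
    chrom = "chrSim",
    start = (seq_along(specs) - 1L) * (L + gap),
    end   = (seq_along(specs) - 1L) * (L + gap) + L,
    intron_id = vapply(specs, `[[`, character(1), "id"),
    gene = paste0("gene_", vapply(specs, `[[`, character(1), "id"))
  )
  depth_rows <- purrr::imap(specs, function(s, i) {
    st <- introns$start[i]
    ncov <- round(s$cov * L)
    out <- tibble(chrom = "chrSim", start = st, end = st + ncov, depth = s$depth)
    # uncovered remainder is simply absent from the track (depth 0 imputed)
    out[out$end > out$start, ]
  }) |> bind_rows()
  junctions <- tibble(
    intron_id = introns$intron_id,
    junction_reads = vapply(specs, function(s) as.integer(s$junc), integer(1))
  )
  list(introns = introns, depth = depth_rows, junctions = junctions,
       truth = introns$intron_id[vapply(specs, `[[`, logical(1), "retained")])
}

#' Write a full simulated dataset to disk
#'
#' Emits the files the pipeline stages read: `expression.tsv`,
#' `metadata.tsv`, `secreted.txt`, `introns.bed`, `depth.bedgraph`,
#' `junctions.tsv` and `truth.json`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
sim_write <- function(config = sim_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- sim_design(config)
  sim <- sim_expression(design, config)
  ir <- sim_intron_fixtures(config)
  write_expression(sim$expr, file.path(dir, "expression.tsv"))
  readr::write_tsv(design, file.path(dir, "metadata.tsv"), progress = FALSE)
  writeLines(sim$truth$secreted, file.path(dir, "secreted.txt"))
  write_bed(ir$introns, file.path(dir, "introns.bed"))
  write_bedgraph(ir$depth, file.path(dir, "depth.bedgraph"))
  readr::write_tsv(ir$junctions, file.path(dir, "junctions.tsv"), progress = FALSE)
  truth <- sim$truth
  truth$retained_introns <- ir$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = FALSE)
  invisible(dir)
}

#' Write intron intervals as BED (0-based half-open)
#' @param introns Tibble with `chrom`, `start`, `end`, `intron_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(introns, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", introns$chrom, introns$start,
                   introns$end, introns$intron_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write a depth track as bedGraph
#' @param depth Tibble with `chrom`, `start`, `end`, `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(depth, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", depth$chrom, depth$start, depth$end,
                   format(depth$depth, trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}
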