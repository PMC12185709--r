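#' Run the full analysis pipeline from one config
#'
#' Stages, in order: `simulate` (or load user-supplied inputs), `de` +
#' `sexbias`, `attenuation`, `crosstalk`, `ir`, `enrich`. Each stage
#' writes its outputs under its own subdirectory of `out_dir`; a JSON run
#' manifest records the config snapshot, input digests, per-stage row
#' counts, wall times and warnings. Deterministic stages are byte-stable:
#' re-running with the same config and seed reproduces identical TSVs.
#'
#' The config is a YAML file (or an equivalent named list) with blocks:
#' \describe{
#'   \item{seed}{integer; expanded per-stage by a fixed offset so stages
#'     are independently reproducible.}
#'   \item{simulate}{either `true` (defaults) or a list of [sim_config()]
#'     fields; mutually exclusive with `inputs`.}
#'   \item{inputs}{paths `expression`, `metadata`, `secreted`, `introns`,
#'     `depth`, `junctions` for user data.}
#'   \item{dimorphism}{`organ` (default liver) for the sex-bias contrast.}
#'   \item{crosstalk}{`origin`, `target`, `r_thresh`, `p_thresh`.}
#'   \item{enrich}{`gmt` path; stage skipped when absent.}
#' }
#'
#' @param config Path to a YAML config, or a named list.
#' @param out_dir Output directory.
#' @return The manifest (list), invisibly; all outputs on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    config_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    # resolve relative input paths against the config file location
    resolve <- function(p) {
      if (is.null(p) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(config_dir, p)
    }
    config$inputs <- lapply(config$inputs, resolve)
    config$enrich$gmt <- resolve(config$enrich$gmt)
  }
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  manifest <- list(config = config, seed = seed, started = format(Sys.time()),
                   stages = list())
  log_stage <- function(name, t0, counts, warnings = character(0)) {
    manifest$stages[[name]] <<- list(
      wall_seconds = round(as.numeric(Sys.time()) - t0, 3),
      rows = counts, warnings = warnings)
    message(sprintf("[%s] done in %.1fs (%s)", name,
                    manifest$stages[[name]]$wall_seconds,
                    paste(names(counts), unlist(counts), sep = "=", collapse = ", ")))
  }

  # --- inputs -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (isTRUE(config$simulate) || is.list(config$simulate)) {
    sim_args <- if (is.list(config$simulate)) config$simulate else list()
    sim_args$seed <- stage_seed(seed, "simulate")
    cfg <- do.call(sim_config, sim_args)
    sim_dir <- file.path(out_dir, "simulate")
    sim_write(cfg, sim_dir)
    paths <- list(expression = file.path(sim_dir, "expression.tsv"),
                  metadata = file.path(sim_dir, "metadata.tsv"),
                  secreted = file.path(sim_dir, "secreted.txt"),
                  introns = file.path(sim_dir, "introns.bed"),
                  depth = file.path(sim_dir, "depth.bedgraph"),
                  junctions = file.path(sim_dir, "junctions.tsv"))
  } else {
    paths <- config$inputs
  }
  expr <- read_expression(paths$expression)
  meta <- read_metadata(paths$metadata)
  secreted <- read_gene_list(paths$secreted)
  manifest$inputs <- lapply(paths, function(p) unname(tools::md5sum(p)))
  log_stage("inputs", t0, list(genes = nrow(expr), samples = ncol(expr)))

  # --- dimorphism ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  dim_dir <- file.path(out_dir, "dimorphism"); dir.create(dim_dir, showWarnings = FALSE)
  organ_dim <- config$dimorphism$organ %||% "liver"
  sel <- function(org, grp, sx) {
    meta$sample_id[meta$organ == org & meta$group == grp & meta$sex == sx]
  }
  de_ca <- de_test_samples(expr, sel(organ_dim, "CA", "female"), sel(organ_dim, "CA", "male"))
  bias <- classify_sex_bias(de_ca)
  de_m <- de_test_samples(expr, sel(organ_dim, "CA", "male"), sel(organ_dim, "WA", "male"))
  de_f <- de_test_samples(expr, sel(organ_dim, "CA", "female"), sel(organ_dim, "WA", "female"))
  atten <- attenuation_analysis(bias, de_m, de_f)
  grid <- deg_count_grid(expr, meta)
  readr::write_tsv(as_tibble(bias), file.path(dim_dir, "sex_bias.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(atten), file.path(dim_dir, "attenuation.tsv"), progress = FALSE)
  readr::write_tsv(grid, file.path(dim_dir, "deg_grid.tsv"), progress = FALSE)
  log_stage("dimorphism", t0, list(biased = sum(bias$bias != "unbiased"),
                                   grid_cells = nrow(grid)))

  # --- crosstalk ----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  ct_dir <- file.path(out_dir, "crosstalk"); dir.create(ct_dir, showWarnings = FALSE)
  ct <- rank_regulators(
    expr, meta, secreted,
    origin_organ = config$crosstalk$origin %||% "liver",
    target_organ = config$crosstalk$target %||% "small_intestine",
    r_thresh = config$crosstalk$r_thresh %||% 0.5,
    p_thresh = config$crosstalk$p_thresh %||% 0.05)
  readr::write_tsv(ct$scores, file.path(ct_dir, "regulators.tsv"), progress = FALSE)
  readr::write_tsv(ct$targets, file.path(ct_dir, "targets.tsv"), progress = FALSE)
  log_stage("crosstalk", t0, list(secreted = nrow(ct$scores),
                                  selected_pairs = nrow(ct$targets)))

  # --- intron retention ---------------------------------------------------
  t0 <- as.numeric(Sys.time())
  ir_dir <- file.path(out_dir, "ir"); dir.create(ir_dir, showWarnings = FALSE)
  introns <- read_bed(paths$introns)
  depth <- read_bedgraph(paths$depth)
  juncs <- read_junctions(paths$junctions)
  recs <- score_introns(introns, depth, juncs)
  readr::write_tsv(as_tibble(recs), file.path(ir_dir, "intron_records.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(filter_introns(recs)),
                   file.path(ir_dir, "retained.tsv"), progress = FALSE)
  log_stage("ir", t0, list(introns = nrow(recs), retained = sum(recs$retained)))

  # --- enrichment ---------------------------------------------------------
  if (!is.null(config$enrich$gmt)) {
    t0 <- as.numeric(Sys.time())
    en_dir <- file.path(out_dir, "enrich"); dir.create(en_dir, showWarnings = FALSE)
    sets <- read_gmt(config$enrich$gmt)
    en <- enrich_targets(ct, sets)
    readr::write_tsv(as_tibble(en), file.path(en_dir, "enrichment.tsv"), progress = FALSE)
    log_stage("enrich", t0, list(terms = nrow(en), significant = sum(en$significant)))
  }

  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

validate_pipeline_config <- function(config) {
  has_sim <- isTRUE(config$simulate) || is.list(config$simulate)
  if (!has_sim) {
    req <- c("expression", "metadata", "secreted", "introns", "depth", "junctions")
    missing <- setdiff(req, names(config$inputs))
    if (length(missing) > 0) {
      abort(paste0("config has no simulate block and inputs are missing: ",
                   paste(missing, collapse = ", ")), class = "interorgan_config_error")
    }
    absent <- unlist(config$inputs[req])[!file.exists(unlist(config$inputs[req]))]
    if (length(absent) > 0) {
      abort(paste0("input file(s) not found: ", paste(absent, collapse = ", ")),
            class = "interorgan_config_error")
    }
  }
  invisible(config)
}

# Per-stage seed derivation: global seed plus a fixed stage-name offset
# (sum of character codes), kept within 32-bit integer range.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + sum(utf8ToInt(stage)) * 1000) %% .Machine$integer.max)
}
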