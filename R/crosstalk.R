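#' Significance score of a secreted gene against a target organ
#'
#' The score sums the significance levels of the correlations with every
#' gene expressed in the target organ: score = sum_j -log10(p_j), over ALL
#' target genes, not just those passing selection thresholds. P-values are
#' floored at `p_floor` so the score stays finite.
#'
#' @param p_row P-values over target-organ genes.
#' @param p_floor Lower floor applied before the logarithm.
#' @return Non-negative scalar.
#' @export
significance_score <- function(p_row, p_floor = 1e-300) {
  if (length(p_row) == 0) abort("empty p-value row", class = "interorgan_error")
  if (any(is.na(p_row)) || any(p_row < 0) || any(p_row > 1)) {
    abort("p-values must lie in [0, 1] and be non-missing", class = "interorgan_error")
  }
  sum(-log10(pmax(p_row, p_floor)))
}

#' Origin-organ specificity of candidate secreted regulators
#'
#' A candidate passes when its mean FPKM across origin-organ samples
#' strictly exceeds its mean FPKM in every other organ — the "primarily
#' expressed by the origin organ" requirement. Ties fail.
#'
#' @param genes Gene ids to test.
#' @param expr Expression matrix (FPKM).
#' @param meta Sample metadata.
#' @param origin_organ Organ proposed as the source.
#' @return Named logical vector over `genes`.
#' @export
specificity_filter <- function(genes, expr, meta, origin_organ) {
  meta <- align_metadata(expr, validate_metadata(meta))
  organs <- unique(meta$organ)
  if (!origin_organ %in% organs) {
    abort(paste0("origin organ '", origin_organ, "' has zero samples"),
          class = "interorgan_error")
  }
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0) {
    abort(paste0("gene(s) absent from expression matrix: ",
                 paste(head(missing, 5), collapse = ", ")), class = "interorgan_error")
  }
  sub <- expr[genes, , drop = FALSE]
  organ_means <- vapply(organs, function(o) {
    rowMeans(sub[, meta$organ == o, drop = FALSE])
  }, numeric(length(genes)))
  if (length(genes) == 1) organ_means <- matrix(organ_means, nrow = 1,
                                                dimnames = list(genes, organs))
  others <- setdiff(organs, origin_organ)
  pass <- organ_means[, origin_organ] > apply(organ_means[, others, drop = FALSE], 1, max)
  setNames(as.logical(pass), genes)
}

#' Rank secreted-protein genes as candidate inter-organ regulators
#'
#' The screening pipeline for one origin -> target organ comparison:
#' origin and target samples are paired by animal, every secreted gene is
#' correlated (biweight midcorrelation) with every target-organ gene, each
#' secreted gene receives the sum of -log10 p over all target genes as its
#' significance score, genes are ranked by descending score (ties broken
#' by gene id), the origin-specificity filter is applied to the ranked
#' list, and per-gene target genes are selected at `r > r_thresh` and
#' `p < p_thresh` (both strict).
#'
#' @param expr Expression matrix holding both organs' samples.
#' @param meta Sample metadata.
#' @param secreted Character vector of secreted-protein gene ids (must
#'   intersect the matrix rows).
#' @param origin_organ,target_organ The organ pair.
#' @param r_thresh,p_thresh Target-selection thresholds.
#' @param p_floor Floor under p-values before -log10.
#' @param log_transform Correlate on log2(FPKM + 1) (default). FPKM spans
#'   orders of magnitude; on the log scale expression relationships are
#'   close to linear and the correlation screen is not dominated by a few
#'   highly expressed samples. Set `FALSE` to screen raw FPKM.
#' @return Object of class `crosstalk_result`: list with `scores` (tibble:
#'   `secreted_gene`, `score`, `rank`, `passed_specificity`, `n_targets`),
#'   `targets` (tibble: `secreted_gene`, `target_gene`, `r`, `p`),
#'   `n_target_genes`, `n_animals`, and the thresholds.
#' @export
rank_regulators <- function(expr, meta, secreted,
                            origin_organ = "liver",
                            target_organ = "small_intestine",
                            r_thresh = 0.5, p_thresh = 0.05,
                            p_floor = 1e-300, log_transform = TRUE) {
  meta <- validate_metadata(meta)
  secreted <- unique(secreted)
  absent <- setdiff(secreted, rownames(expr))
  if (length(absent) == length(secreted)) {
    abort("no secreted gene present in the expression matrix", class = "interorgan_error")
  }
  if (length(absent) > 0) {
    warn(paste0(length(absent), " secreted gene(s) absent from matrix and skipped"))
    secreted <- setdiff(secreted, absent)
  }
  paired <- pair_by_animal(expr, meta, origin_organ, target_organ)
  a <- paired$origin[secreted, , drop = FALSE]
  b <- paired$target
  if (log_transform) { a <- log2(a + 1); b <- log2(b + 1) }
  screen <- bicor_screen(a, b)
  # constant target genes carry no correlation information; count them as p = 1
  screen$p[is.na(screen$p)] <- 1
  scores <- apply(screen$p, 1, significance_score, p_floor = p_floor)
  ord <- order(-scores, names(scores))
  score_tbl <- tibble(secreted_gene = names(scores)[ord],
                      score = unname(scores)[ord],
                      rank = seq_along(scores))
  spec <- specificity_filter(score_tbl$secreted_gene, expr, meta, origin_organ)
  score_tbl$passed_specificity <- unname(spec[score_tbl$secreted_gene])
  sel <- which(screen$r > r_thresh & screen$p < p_thresh, arr.ind = TRUE)
  targets <- tibble(
    secreted_gene = rownames(screen$r)[sel[, 1]],
    target_gene = colnames(screen$r)[sel[, 2]],
    r = screen$r[sel], p = screen$p[sel]
  ) |> arrange(.data$secreted_gene, desc(.data$r))
  score_tbl$n_targets <- vapply(score_tbl$secreted_gene, function(g) {
    sum(targets$secreted_gene == g)
  }, integer(1))
  structure(
    list(scores = score_tbl, targets = targets,
         target_universe = colnames(screen$r),
         n_target_genes = ncol(screen$r), n_animals = screen$n,
         origin_organ = origin_organ, target_organ = target_organ,
         r_thresh = r_thresh, p_thresh = p_thresh, p_floor = p_floor),
    class = "crosstalk_result"
  )
}

#' @export
print.crosstalk_result <- function(x, ...) {
  cat(sprintf("crosstalk screen: %s -> %s, %d secreted genes vs %d target genes, n = %d animals\n",
              x$origin_organ, x$target_organ, nrow(x$scores), x$n_target_genes, x$n_animals))
  cat(sprintf("target selection: r > %g, p < %g\n", x$r_thresh, x$p_thresh))
  print(head(x$scores, 10))
  invisible(x)
}

#' Tidy a crosstalk screen
#'
#' @param x A `crosstalk_result`.
#' @param ... Unused.
#' @return The per-secreted-gene score tibble.
#' @method tidy crosstalk_result
#' @export
tidy.crosstalk_result <- function(x, ...) x$scores

#' @method glance crosstalk_result
#' @export
glance.crosstalk_result <- function(x, ...) {
  tibble(n_secreted = nrow(x$scores),
         n_target_genes = x$n_target_genes,
         n_animals = x$n_animals,
         top_gene = x$scores$secreted_gene[1],
         top_score = x$scores$score[1],
         n_selected_pairs = nrow(x$targets))
}

#' Enrichment of a regulator's selected target genes
#'
#' Delegates to [hypergeom_enrich()] with background = all target-organ
#' genes screened. An empty target list yields an empty result with a
#' warning rather than an error.
#'
#' @param result A [rank_regulators()] result.
#' @param gene_sets A [read_gmt()] collection.
#' @param secreted_gene Which regulator's targets to test (default: rank
#'   1).
#' @param background Optional explicit background; defaults to all genes
#'   screened in the target organ (recorded in `result`).
#' @return An enrichment tibble (see [hypergeom_enrich()]).
#' @export
enrich_targets <- function(result, gene_sets, secreted_gene = NULL,
                           background = NULL) {
  if (is.null(secreted_gene)) secreted_gene <- result$scores$secreted_gene[1]
  fg <- result$targets$target_gene[result$targets$secreted_gene == secreted_gene]
  if (length(fg) == 0) {
    warn(paste0("no selected targets for ", secreted_gene, "; empty enrichment"))
    return(empty_enrichment())
  }
  if (is.null(background)) background <- result$target_universe
  if (is.null(background)) {
    abort("supply `background` (all screened target-organ genes)", class = "interorgan_error")
  }
  hypergeom_enrich(fg, background, gene_sets)
}
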