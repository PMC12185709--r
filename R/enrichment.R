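#' Hypergeometric over-representation test over a gene-set collection
#'
#' For each set, with N background genes, K of them in the set, n
#' foreground genes and k foreground hits, the p-value is the upper tail
#' including the observed count: p = P(X >= k) =
#' sum_{i >= k} C(K, i) C(N-K, n-i) / C(N, n). Sets are intersected with
#' the background before testing; sets that vanish after intersection are
#' skipped. Q-values are Benjamini-Hochberg over the tested terms; terms
#' with q below `alpha` are flagged significant.
#'
#' @param foreground Gene ids of interest; must be a subset of
#'   `background`.
#' @param background All genes that could have been selected (the tested
#'   universe).
#' @param gene_sets Collection from [read_gmt()].
#' @param alpha Significance threshold on q.
#' @return Tibble of class `enrichment_result`, sorted by q then p:
#'   `term`, `term_name`, `k`, `K`, `n`, `N`, `p`, `q`, `significant`.
#' @export
hypergeom_enrich <- function(foreground, background, gene_sets, alpha = 0.05) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (length(foreground) == 0) abort("empty foreground", class = "interorgan_error")
  stray <- setdiff(foreground, background)
  if (length(stray) > 0) {
    abort(paste0("foreground gene(s) not in background: ",
                 paste(head(stray, 5), collapse = ", ")), class = "interorgan_error")
  }
  N <- length(background)
  n <- length(foreground)
  rows <- purrr::imap(gene_sets, function(s, term) {
    set_genes <- intersect(s$genes, background)
    K <- length(set_genes)
    if (K == 0) return(NULL)
    k <- length(intersect(set_genes, foreground))
    # upper tail including k: P(X >= k)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term = term, term_name = s$term_name, k = k, K = K, n = n, N = N, p = p)
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) return(empty_enrichment())
  out <- bind_rows(rows) |>
    mutate(q = p.adjust(.data$p, method = "BH"),
           significant = .data$q < alpha) |>
    arrange(.data$q, .data$p)
  class(out) <- c("enrichment_result", class(tibble()))
  out
}

empty_enrichment <- function() {
  out <- tibble(term = character(0), term_name = character(0),
                k = integer(0), K = integer(0), n = integer(0), N = integer(0),
                p = numeric(0), q = numeric(0), significant = logical(0))
  class(out) <- c("enrichment_result", class(tibble()))
  out
}

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_terms = nrow(x), n_significant = sum(x$significant),
         min_q = if (nrow(x)) min(x$q) else NA_real_)
}
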