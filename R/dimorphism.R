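#' Two-group differential expression on log2(FPKM + 1)
#'
#' The differential-expression stage is a contract: any test producing a
#' per-gene log2 fold-change, p-value and BH-adjusted p fits downstream.
#' The default implementation is a Welch two-sample t-test on
#' log2(FPKM + 1); fold-change is mean(B) - mean(A) on that scale. This
#' deliberately is not a count-model test, so absolute DEG counts from it
#' are not comparable to negative-binomial engines run on raw counts.
#'
#' Group selectors are data-masked expressions evaluated against the
#' metadata, e.g. `group == "CA" & sex == "male" & organ == "liver"`.
#'
#' @param expr Expression matrix (genes x samples), FPKM scale.
#' @param meta Sample metadata.
#' @param a,b Selector expressions for the two groups (fold-change is B vs
#'   A).
#' @return Tibble of class `de_result`: `gene`, `log2fc`, `p`, `padj`
#'   (BH over all tested genes).
#' @export
de_test <- function(expr, meta, a, b) {
  meta <- validate_metadata(meta)
  sa <- dplyr::filter(meta, !!rlang::enquo(a))$sample_id
  sb <- dplyr::filter(meta, !!rlang::enquo(b))$sample_id
  de_test_samples(expr, sa, sb)
}

#' @rdname de_test
#' @param samples_a,samples_b Explicit sample id vectors (the programmatic
#'   interface behind [de_test()]).
#' @export
de_test_samples <- function(expr, samples_a, samples_b) {
  if (length(samples_a) == 0 || length(samples_b) == 0) {
    abort("a group selector matched no samples", class = "interorgan_error")
  }
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    abort("need >= 2 samples on each side", class = "interorgan_error")
  }
  missing <- setdiff(c(samples_a, samples_b), colnames(expr))
  if (length(missing) > 0) {
    abort(paste0("samples absent from expression matrix: ",
                 paste(head(missing, 5), collapse = ", ")), class = "interorgan_error")
  }
  la <- log2(expr[, samples_a, drop = FALSE] + 1)
  lb <- log2(expr[, samples_b, drop = FALSE] + 1)
  n1 <- ncol(la); n2 <- ncol(lb)
  m1 <- rowMeans(la); m2 <- rowMeans(lb)
  v1 <- rowSums((la - m1)^2) / (n1 - 1)
  v2 <- rowSums((lb - m2)^2) / (n2 - 1)
  log2fc <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  t <- log2fc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df = df)
  # degenerate genes: no variance on either side
  flat <- v1 == 0 & v2 == 0
  p[flat & log2fc == 0] <- 1
  p[flat & log2fc != 0] <- 0
  log2fc[flat & log2fc == 0] <- 0
  out <- tibble(gene = rownames(expr), log2fc = unname(log2fc), p = unname(p),
                padj = unname(p.adjust(p, method = "BH")))
  class(out) <- c("de_result", class(out))
  out
}

#' Classify genes as male-/female-biased or unbiased
#'
#' Applied to the cool-acclimated male-vs-female contrast (convention:
#' fold-change is male vs female, so log2fc > 1 means male-biased). Biased
#' iff |log2fc| > `lfc` AND padj < `alpha`, both strict.
#'
#' @param de A [de_test()] result for the male-vs-female contrast
#'   (`a = female`, `b = male` so that log2fc is male vs female).
#' @param lfc Fold-change threshold, log2 units.
#' @param alpha Adjusted-p threshold.
#' @return Tibble of class `sex_bias_table`: the DE columns plus `bias`
#'   in {male_biased, female_biased, unbiased}.
#' @export
classify_sex_bias <- function(de, lfc = 1, alpha = 0.05) {
  out <- de |>
    mutate(bias = dplyr::case_when(
      .data$log2fc > lfc & .data$padj < alpha ~ "male_biased",
      .data$log2fc < -lfc & .data$padj < alpha ~ "female_biased",
      TRUE ~ "unbiased"
    ))
  class(out) <- c("sex_bias_table", "de_result", class(tibble()))
  out
}

#' Male-vs-female DEG counts per organ and group
#'
#' Counts genes passing |log2fc| > `lfc` and padj < `alpha` in the
#' male-vs-female contrast, separately in every organ x group cell. An
#' organ or group absent from the data yields NA with a warning.
#'
#' @param expr Expression matrix.
#' @param meta Sample metadata.
#' @param lfc,alpha Thresholds as in [classify_sex_bias()].
#' @return Tibble with `organ`, `group`, `n_deg`.
#' @export
deg_count_grid <- function(expr, meta, lfc = 1, alpha = 0.05) {
  meta <- validate_metadata(meta)
  organs <- intersect(ORGANS, unique(meta$organ))
  grid <- tidyr::expand_grid(organ = organs, group = GROUPS)
  counts <- purrr::pmap_dbl(grid, function(organ, group) {
    mm <- meta[meta$organ == organ & meta$group == group, ]
    sf <- mm$sample_id[mm$sex == "female"]
    sm <- mm$sample_id[mm$sex == "male"]
    if (length(sf) < 2 || length(sm) < 2) {
      warn(paste0("organ ", organ, ", group ", group,
                  ": too few samples per sex; reporting NA"))
      return(NA_real_)
    }
    de <- de_test_samples(expr, sf, sm)
    sum(abs(de$log2fc) > lfc & de$padj < alpha, na.rm = TRUE)
  })
  grid |> mutate(n_deg = counts)
}

#' Directional attenuation of sexual dimorphism under warming
#'
#' Given the cool-reference sex-bias classes and the warm-vs-cool
#' differential results computed within each sex, asks whether warming
#' moves biased genes toward the opposite sex: in males the expected sign
#' of the warm-vs-cool fold-change is negative for male-biased genes and
#' positive for female-biased genes; in females the pattern mirrors. Each
#' class x sex cell gets the median fold-change, the fraction of genes with
#' the expected sign, and a two-sided sign-test p (ties at zero dropped).
#'
#' @param bias A [classify_sex_bias()] table from the cool-acclimated
#'   reference.
#' @param de_male Warm-vs-cool [de_test()] result within males (log2fc =
#'   warm vs cool).
#' @param de_female Same within females.
#' @return Tibble of class `attenuation_summary`: `sex`, `bias`,
#'   `n_genes`, `median_log2fc`, `frac_expected_sign`, `sign_test_p`.
#'   Per-gene fold-changes are kept in the `"details"` attribute for
#'   plotting.
#' @export
attenuation_analysis <- function(bias, de_male, de_female) {
  biased <- bias |> filter(.data$bias != "unbiased") |> select("gene", "bias")
  details <- bind_rows(
    biased |> inner_join(de_male, by = "gene") |> mutate(sex = "male"),
    biased |> inner_join(de_female, by = "gene") |> mutate(sex = "female")
  ) |>
    mutate(expected_sign = ifelse(
      (.data$sex == "male") == (.data$bias == "male_biased"), -1, 1))
  grid <- tidyr::expand_grid(sex = SEXES, bias = c("male_biased", "female_biased"))
  out <- purrr::pmap(grid, function(sex, bias) {
    d <- details[details$sex == sex & details$bias == bias, ]
    if (nrow(d) == 0) {
      return(tibble(sex = sex, bias = bias, n_genes = 0L,
                    median_log2fc = NA_real_, frac_expected_sign = NA_real_,
                    sign_test_p = NA_real_))
    }
    nonzero <- d$log2fc != 0
    hits <- sum(sign(d$log2fc[nonzero]) == d$expected_sign[nonzero])
    pv <- if (sum(nonzero) > 0) binom.test(hits, sum(nonzero), p = 0.5)$p.value else NA_real_
    tibble(sex = sex, bias = bias, n_genes = nrow(d),
           median_log2fc = median(d$log2fc),
           frac_expected_sign = mean(sign(d$log2fc) == d$expected_sign),
           sign_test_p = pv)
  }) |> bind_rows()
  attr(out, "details") <- details
  class(out) <- c("attenuation_summary", class(tibble()))
  out
}

#' @method glance sex_bias_table
#' @export
glance.sex_bias_table <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_male_biased = sum(x$bias == "male_biased"),
         n_female_biased = sum(x$bias == "female_biased"),
         n_unbiased = sum(x$bias == "unbiased"))
}

#' @method glance attenuation_summary
#' @export
glance.attenuation_summary <- function(x, ...) {
  tibble(n_cells = nrow(x),
         all_expected = all(x$frac_expected_sign > 0.5, na.rm = TRUE),
         max_sign_test_p = max(x$sign_test_p, na.rm = TRUE))
}
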