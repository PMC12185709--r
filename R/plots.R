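#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_histogram
#'   geom_errorbar geom_hline geom_vline geom_boxplot labs theme_minimal
#'   facet_grid autoplot position_dodge scale_colour_manual
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Score distribution of a crosstalk screen
#'
#' Histogram of significance scores over secreted genes, with the
#' top-ranked gene marked.
#'
#' @param object A [rank_regulators()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot crosstalk_result
#' @export
autoplot.crosstalk_result <- function(object, ...) {
  df <- object$scores
  top <- df[df$rank == 1, ]
  ggplot(df, aes(x = .data$score)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = top$score, linetype = "dashed", colour = "firebrick") +
    labs(x = "significance score (sum of -log10 p over target-organ genes)",
         y = "secreted genes",
         title = sprintf("%s -> %s crosstalk screen (top: %s)",
                         object$origin_organ, object$target_organ,
                         top$secreted_gene)) +
    theme_minimal()
}

#' Volcano plot of sex-biased expression
#'
#' @param object A [classify_sex_bias()] table.
#' @param lfc,alpha Thresholds drawn as guide lines.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sex_bias_table
#' @export
autoplot.sex_bias_table <- function(object, lfc = 1, alpha = 0.05, ...) {
  ggplot(object, aes(x = .data$log2fc, y = -log10(pmax(.data$padj, 1e-300)),
                     colour = .data$bias)) +
    geom_point(size = 0.8, alpha = 0.7) +
    geom_vline(xintercept = c(-lfc, lfc), linetype = "dotted") +
    geom_hline(yintercept = -log10(alpha), linetype = "dotted") +
    scale_colour_manual(values = c(male_biased = "#c0392b",
                                   female_biased = "#27ae60",
                                   unbiased = "grey70")) +
    labs(x = "log2 fold-change (male vs female)", y = "-log10 adjusted p",
         colour = NULL) +
    theme_minimal()
}

#' Warm-vs-cool fold-change by sex-bias class
#'
#' Boxplots of per-gene warm-vs-cool log2 fold-changes, split by bias
#' class and sex; directional attenuation shows as male-biased genes
#' falling in warm males and rising in warm females (mirrored for
#' female-biased genes).
#'
#' @param object An [attenuation_analysis()] summary (per-gene detail is
#'   carried in its `"details"` attribute).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot attenuation_summary
#' @export
autoplot.attenuation_summary <- function(object, ...) {
  details <- attr(object, "details")
  ggplot(details, aes(x = .data$bias, y = .data$log2fc, fill = .data$bias)) +
    geom_boxplot(outlier.size = 0.5) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    facet_grid(. ~ sex) +
    labs(x = NULL, y = "log2 fold-change (warm vs cool)") +
    theme_minimal()
}

#' Retention-ratio bar plot per group
#'
#' Mean retention ratio with SEM error bars for each intron and group.
#'
#' @param summary An [ir_group_summary()] tibble.
#' @return A ggplot.
#' @export
plot_ir_summary <- function(summary) {
  ggplot(summary, aes(x = .data$group, y = .data$mean_ratio, fill = .data$group)) +
    geom_col() +
    geom_errorbar(aes(ymin = .data$mean_ratio - .data$sem,
                      ymax = .data$mean_ratio + .data$sem), width = 0.3) +
    facet_grid(. ~ intron_id) +
    labs(x = NULL, y = "intron retention ratio (mean ± SEM)") +
    theme_minimal()
}

#' DEG-count grid plot
#'
#' Male-vs-female DEG counts per organ across the four groups.
#'
#' @param grid A [deg_count_grid()] tibble.
#' @return A ggplot.
#' @export
plot_deg_grid <- function(grid) {
  grid$group <- factor(grid$group, levels = GROUPS)
  ggplot(grid, aes(x = .data$group, y = .data$n_deg, fill = .data$group)) +
    geom_col() +
    facet_grid(. ~ organ) +
    labs(x = NULL, y = "male-vs-female DEGs") +
    theme_minimal()
}
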