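#' Intron-retention evidence for one intron
#'
#' From a per-base depth vector over the intron and the spliced-junction
#' read count spanning it, computes:
#' * `intron_depth` — trimmed median per-base depth: positions are sorted
#'   by depth, the lowest and highest 10% (floor) are discarded, and the
#'   median of the rest taken. The trim suppresses exon-bleed at intron
#'   edges without needing read-level data.
#' * `coverage` — fraction of intron bases with depth > 0.
#' * `ir_ratio` — intron_depth / (intron_depth + junction_reads); when
#'   both terms are 0 the ratio is defined as 0 (no evidence at all).
#'
#' @param depth Numeric vector, one value per intron base, length >= 1.
#' @param junction_reads Count of spliced reads spanning the intron.
#' @param trim Fraction trimmed from each end of the sorted depths.
#' @return One-row tibble: `intron_depth`, `coverage`, `ir_ratio`.
#' @export
ir_ratio <- function(depth, junction_reads, trim = 0.1) {
  if (length(depth) < 1) abort("empty interval", class = "interorgan_error")
  if (junction_reads < 0) abort("negative junction count", class = "interorgan_error")
  intron_depth <- trimmed_median(depth, trim)
  coverage <- mean(depth > 0)
  ratio <- if (intron_depth == 0 && junction_reads == 0) 0 else
    intron_depth / (intron_depth + junction_reads)
  tibble(intron_depth = intron_depth, coverage = coverage, ir_ratio = ratio)
}

trimmed_median <- function(x, trim = 0.1) {
  k <- floor(trim * length(x))
  s <- sort(x)
  if (2 * k >= length(x)) return(median(s))
  median(s[(k + 1):(length(x) - k)])
}

#' Score all introns of a sample
#'
#' Joins intervals, depth track and junction counts into per-intron
#' records with the retention call.
#'
#' @param introns Interval tibble from [read_bed()].
#' @param depth_track Depth tibble from [read_bedgraph()].
#' @param junctions Junction tibble from [read_junctions()].
#' @inheritParams filter_introns
#' @param trim Trim fraction for the depth median.
#' @return Tibble of class `ir_records`: interval columns plus
#'   `junction_reads`, `intron_depth`, `coverage`, `ir_ratio`, `retained`.
#' @export
score_introns <- function(introns, depth_track, junctions,
                          ratio_min = 0.5, coverage_min = 0.9, depth_min = 1,
                          trim = 0.1) {
  missing <- setdiff(introns$intron_id, junctions$intron_id)
  if (length(missing) > 0) {
    abort(paste0("introns without junction counts: ",
                 paste(head(missing, 5), collapse = ", ")), class = "interorgan_error")
  }
  recs <- introns |>
    left_join(junctions, by = "intron_id") |>
    mutate(purrr::pmap_dfr(
      list(.data$chrom, .data$start, .data$end, .data$junction_reads),
      function(chrom, start, end, junction_reads) {
        ir_ratio(depth_vector(depth_track, chrom, start, end), junction_reads, trim = trim)
      }))
  recs <- recs |>
    mutate(retained = .data$ir_ratio > ratio_min &
             .data$coverage > coverage_min &
             .data$intron_depth > depth_min)
  class(recs) <- c("ir_records", class(tibble()))
  recs
}

#' Three-threshold retention filter
#'
#' Keeps introns with retention ratio > `ratio_min`, base coverage >
#' `coverage_min` and trimmed-median depth > `depth_min` — all strict, so
#' records sitting exactly at a threshold are excluded. Order is
#' preserved; the filter is a pure predicate.
#'
#' @param records An [score_introns()] tibble (needs `ir_ratio`,
#'   `coverage`, `intron_depth`).
#' @param ratio_min Retention-ratio threshold.
#' @param coverage_min Coverage threshold.
#' @param depth_min Depth threshold.
#' @return The retained subset, same columns and order.
#' @export
filter_introns <- function(records, ratio_min = 0.5, coverage_min = 0.9,
                           depth_min = 1) {
  keep <- records$ir_ratio > ratio_min &
    records$coverage > coverage_min &
    records$intron_depth > depth_min
  records[keep, , drop = FALSE]
}

#' Per-group mean and SEM of retention ratios
#'
#' @param records_by_sample Tibble of per-sample intron records with
#'   columns `sample_id`, `intron_id`, `ir_ratio`.
#' @param meta Sample metadata.
#' @return Tibble: `intron_id`, `group`, `n`, `mean_ratio`, `sem` (NA when
#'   n = 1).
#' @export
ir_group_summary <- function(records_by_sample, meta) {
  meta <- validate_metadata(meta)
  joined <- records_by_sample |>
    inner_join(meta |> select("sample_id", "group"), by = "sample_id")
  if (nrow(joined) == 0) abort("no samples in common with metadata", class = "interorgan_error")
  joined |>
    group_by(.data$intron_id, .data$group) |>
    summarise(n = dplyr::n(),
              mean_ratio = mean(.data$ir_ratio),
              sem = ifelse(dplyr::n() > 1, sd(.data$ir_ratio) / sqrt(dplyr::n()), NA_real_),
              .groups = "drop")
}
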