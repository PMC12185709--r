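#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows n distinct pull across all_of desc
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median mad sd pt phyper p.adjust binom.test setNames
#' @importFrom utils head tail
NULL

#' Organ, sex and group vocabularies
#'
#' The seven organs sampled in the reciprocal temperature-transfer design,
#' the two sexes, and the four acclimation groups: `CA` cool-acclimated,
#' `CS` cool-switched (warm-reared, switched to cool), `WS` warm-switched
#' (cool-reared, switched to warm), `WA` warm-acclimated.
#'
#' @name vocabularies
#' @keywords internal
ORGANS <- c("brain", "heart", "lung", "liver", "small_intestine", "muscle", "skin")
SEXES  <- c("male", "female")
GROUPS <- c("CA", "CS", "WS", "WA")

stop_io <- function(msg, class = "interorgan_io_error") {
  abort(msg, class = c(class, "interorgan_error"))
}
stop_validation <- function(msg) stop_io(msg, class = "interorgan_validation_error")

#' Read a gene-by-sample expression matrix
#'
#' Reads a TSV whose first column holds gene ids and whose header names the
#' samples; values are FPKM-scale (non-negative, zeros allowed).
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids).
#' @export
read_expression <- function(path) {
  df <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                    progress = FALSE, show_col_types = FALSE),
    error = function(e) stop_io(paste0("failed to parse expression TSV '", path, "': ",
                                       conditionMessage(e)))
  )
  if (ncol(df) < 2) stop_io("expression TSV needs a gene-id column plus at least one sample column")
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    stop_io(paste0("malformed expression TSV at line ", prob$row[1] + 1L, ": ", prob$expected[1]))
  }
  gene_ids <- as.character(df[[1]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) {
    stop_validation(paste0("duplicated gene id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_validation("non-numeric expression values")
  if (anyNA(m)) stop_validation("missing values in expression matrix")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop_validation(paste0("negative FPKM for gene '", gene_ids[bad[1]],
                           "', sample '", colnames(m)[bad[2]], "'"))
  }
  rownames(m) <- gene_ids
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: first column `gene_id`, one column per
#' sample.
#'
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- tibble(gene_id = rownames(x))
  df <- dplyr::bind_cols(df, as_tibble(x))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read and validate sample metadata
#'
#' Requires columns `sample_id`, `animal_id`, `organ`, `sex`, `group`.
#' Organ must be one of the seven sequenced organs; sex one of male/female;
#' group one of CA/CS/WS/WA. Each animal must have a single sex and group
#' and at most one sample per organ.
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per sample.
#' @export
read_metadata <- function(path) {
  df <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE),
    error = function(e) stop_io(paste0("failed to parse metadata TSV '", path, "': ",
                                       conditionMessage(e)))
  )
  if (nrow(df) == 0) stop_validation("metadata file is empty")
  validate_metadata(df)
}

#' Validate a sample metadata table
#'
#' @param df Data frame with the metadata columns (see [read_metadata()]).
#' @return The validated tibble.
#' @export
validate_metadata <- function(df) {
  req <- c("sample_id", "animal_id", "organ", "sex", "group")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop_validation(paste0("metadata missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)[, req]
  bad_organ <- setdiff(unique(df$organ), ORGANS)
  if (length(bad_organ) > 0) {
    stop_validation(paste0("unknown organ(s): ", paste(bad_organ, collapse = ", "),
                           " (expected one of: ", paste(ORGANS, collapse = ", "), ")"))
  }
  bad_sex <- setdiff(unique(df$sex), SEXES)
  if (length(bad_sex) > 0) stop_validation(paste0("unknown sex token(s): ", paste(bad_sex, collapse = ", ")))
  bad_group <- setdiff(unique(df$group), GROUPS)
  if (length(bad_group) > 0) stop_validation(paste0("unknown group token(s): ", paste(bad_group, collapse = ", ")))
  if (anyDuplicated(df$sample_id)) {
    stop_validation(paste0("duplicated sample_id: ",
                           df$sample_id[duplicated(df$sample_id)][1]))
  }
  per_animal <- df |> distinct(.data$animal_id, .data$sex, .data$group)
  if (anyDuplicated(per_animal$animal_id)) {
    bad <- per_animal$animal_id[duplicated(per_animal$animal_id)][1]
    stop_validation(paste0("animal '", bad, "' has inconsistent sex/group across samples"))
  }
  dup_org <- df |> dplyr::count(.data$animal_id, .data$organ) |> filter(.data$n > 1)
  if (nrow(dup_org) > 0) {
    stop_validation(paste0("animal '", dup_org$animal_id[1], "' has multiple '",
                           dup_org$organ[1], "' samples"))
  }
  df
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `term_id<TAB>term_name<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' set are dropped on load; empty sets are rejected.
#'
#' @param path Path to a GMT file.
#' @return Named list of sets; each element has `term_name` and `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_io("GMT file is empty")
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop_io(paste0("GMT line ", i, ": need term id, description and at least one gene"))
    }
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop_validation(paste0("GMT term '", parts[1], "' has no genes"))
    sets[[parts[1]]] <- list(term_name = parts[2], genes = genes)
  }
  sets
}

#' Read intron intervals from BED
#'
#' Coordinates stay 0-based half-open, as in the file. The BED name field
#' (column 4) is interpreted as the owning gene id when present.
#'
#' @param path Path to a BED file.
#' @return Tibble with `chrom`, `start`, `end`, `intron_id`, `gene`.
#' @export
read_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop_io(paste0("failed to parse BED '", path, "': ",
                                                    conditionMessage(e))))
  if (length(gr) == 0) stop_io("BED file has no intervals")
  nm <- if ("name" %in% names(S4Vectors::mcols(gr))) as.character(gr$name) else
    paste0("intron_", seq_along(gr))
  tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # back to 0-based half-open
    end   = BiocGenerics::end(gr),
    intron_id = nm,
    gene = sub("\\..*$", "", nm)
  )
}

#' Read a bedGraph depth track
#'
#' @param path Path to a bedGraph file.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open), `depth`.
#' @export
read_bedgraph <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) stop_io(paste0("failed to parse bedGraph '", path, "': ",
                                                    conditionMessage(e))))
  tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end   = BiocGenerics::end(gr),
    depth = as.numeric(gr$score)
  )
}

#' Extract per-base depth for one interval from a bedGraph track
#'
#' Uncovered bases get depth 0 (bedGraph convention). Bases of the interval
#' must lie within the track's declared chromosome extent only insofar as
#' gaps mean zero; an interval on a chromosome absent from the track is an
#' error.
#'
#' @param track Tibble from [read_bedgraph()].
#' @param chrom,start,end Interval, 0-based half-open.
#' @return Numeric vector of length `end - start`.
#' @export
depth_vector <- function(track, chrom, start, end) {
  if (end <= start) stop_validation("empty interval")
  tr <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(tr) == 0) {
    stop_io(paste0("interval ", chrom, ":", start, "-", end,
                   " lies outside the depth track (chromosome absent)"))
  }
  d <- numeric(end - start)
  keep <- tr$end > start & tr$start < end
  tr <- tr[keep, , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    a <- max(tr$start[i], start) - start + 1L
    b <- min(tr$end[i], end) - start
    d[a:b] <- tr$depth[i]
  }
  d
}

#' Read spliced-junction read counts
#'
#' TSV with columns `intron_id` and `junction_reads` (optionally
#' `sample_id` for multi-sample tables).
#'
#' @param path Path to a TSV file.
#' @return Tibble.
#' @export
read_junctions <- function(path) {
  df <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  req <- c("intron_id", "junction_reads")
  if (!all(req %in% names(df))) {
    stop_validation(paste0("junction table needs columns: ", paste(req, collapse = ", ")))
  }
  if (any(df$junction_reads < 0)) stop_validation("negative junction read count")
  as_tibble(df)
}

#' Read a secreted-protein gene list
#'
#' Plain text, one gene id per line; blank lines and `#` comments ignored.
#'
#' @param path Path to the list.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0) stop_validation("gene list is empty")
  unique(x)
}

# Check expression columns against metadata; returns metadata restricted and
# ordered to the matrix columns.
align_metadata <- function(expr, meta) {
  missing <- setdiff(colnames(expr), meta$sample_id)
  if (length(missing) > 0) {
    stop_validation(paste0("samples absent from metadata: ",
                           paste(head(missing, 5), collapse = ", ")))
  }
  meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
}
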