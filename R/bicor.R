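#' Biweight midcorrelation with t-approximation p-value
#'
#' Robust correlation that downweights points far from the median with Tukey
#' biweights. For a vector x with median m and (unscaled) median absolute
#' deviation d, let u_i = (x_i - m) / (9 d); weights are
#' w_i = (1 - u_i^2)^2 when |u_i| < 1, else 0, and the transformed vector is
#' x~_i = (x_i - m) w_i. The correlation is
#' r = sum(x~ y~) / sqrt(sum(x~^2) sum(y~^2)). A two-sided p-value is taken
#' from t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom.
#'
#' If a vector's MAD is zero the biweight is undefined for it; that vector
#' falls back to ordinary product-moment weighting (centred by the mean,
#' unit weights) and `fallback_used` is set, so large screens never abort on
#' a degenerate gene.
#'
#' @param x,y Numeric vectors of equal length, n >= 4, finite values.
#' @return Object of class `bicor`: list with `r`, `p`, `n`,
#'   `fallback_used`.
#' @examples
#' bicor(c(1, 2, 3, 4, 5, 50), c(2, 4, 6, 8, 10, -1))
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "interorgan_error")
  }
  n <- length(x)
  if (n < 4) abort("need at least 4 paired observations", class = "interorgan_error")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("non-finite values in input", class = "interorgan_error")
  }
  tx <- biweight_transform(x)
  ty <- biweight_transform(y)
  if (tx$constant && ty$constant) {
    abort("both vectors are constant; correlation undefined", class = "interorgan_error")
  }
  if (tx$constant || ty$constant) {
    abort("constant vector; correlation undefined", class = "interorgan_error")
  }
  r <- sum(tx$z * ty$z) / sqrt(sum(tx$z^2) * sum(ty$z^2))
  r <- max(-1, min(1, r))
  structure(
    list(r = r, p = bicor_pvalue(r, n), n = n,
         fallback_used = tx$fallback || ty$fallback),
    class = "bicor"
  )
}

# Biweight transform of one vector. Returns the transformed (weighted,
# centred) values z, whether the MAD-zero fallback was taken, and whether
# the vector is constant (no usable variation under either weighting).
biweight_transform <- function(x) {
  m <- median(x)
  d <- median(abs(x - m))  # unscaled MAD
  if (d == 0) {
    z <- x - mean(x)
    return(list(z = z, fallback = TRUE, constant = all(z == 0)))
  }
  u <- (x - m) / (9 * d)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  z <- (x - m) * w
  list(z = z, fallback = FALSE, constant = all(z == 0))
}

bicor_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

#' @export
print.bicor <- function(x, ...) {
  cat(sprintf("biweight midcorrelation: r = %.4f, p = %.3g, n = %d%s\n",
              x$r, x$p, x$n,
              if (x$fallback_used) " (MAD-zero fallback used)" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a bicor result
#'
#' @param x A `bicor` object.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `p.value`, `n`, `fallback_used`.
#' @method tidy bicor
#' @export
tidy.bicor <- function(x, ...) {
  tibble(estimate = x$r, p.value = x$p, n = x$n, fallback_used = x$fallback_used)
}

#' Screen all row pairs of two expression matrices by bicor
#'
#' Computes bicor between every row of `a` and every row of `b`. Columns of
#' the two matrices must be the same samples in the same order (for
#' cross-organ screens, pair samples by animal first; see
#' [pair_by_animal()]). Element (i, j) equals `bicor(a[i, ], b[j, ])`.
#'
#' @param a,b Numeric matrices, genes x samples, identical column count.
#' @return List with matrices `r` and `p` (rows of `a` x rows of `b`) and
#'   logical vectors `fallback_a`, `fallback_b` flagging rows where the
#'   MAD-zero fallback applied.
#' @export
bicor_screen <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, nrow = 1)
  if (!is.matrix(b)) b <- matrix(b, nrow = 1)
  if (ncol(a) != ncol(b)) {
    abort("matrices must share sample columns", class = "interorgan_error")
  }
  n <- ncol(a)
  if (n < 4) abort("need at least 4 paired samples", class = "interorgan_error")
  ta <- transform_rows(a)
  tb <- transform_rows(b)
  num <- tcrossprod(ta$z, tb$z)                       # sum over samples of za * zb
  den <- sqrt(outer(rowSums(ta$z^2), rowSums(tb$z^2)))
  r <- num / den
  r[!is.finite(r)] <- NA_real_                        # constant rows
  r[r > 1] <- 1; r[r < -1] <- -1
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(t), df = n - 2)
  p[!is.na(r) & abs(r) >= 1] <- 0
  dimnames(r) <- dimnames(p) <- list(rownames(a), rownames(b))
  list(r = r, p = p, n = n, fallback_a = ta$fallback, fallback_b = tb$fallback)
}

# Row-wise biweight transform of a matrix (same rules as the scalar path).
transform_rows <- function(m) {
  med <- apply(m, 1, median)
  ctr <- m - med
  d <- apply(abs(ctr), 1, median)
  fallback <- d == 0
  u <- ctr / (9 * pmax(d, .Machine$double.xmin))
  w <- (1 - u^2)^2 * (abs(u) < 1)
  z <- ctr * w
  if (any(fallback)) {
    zm <- m[fallback, , drop = FALSE]
    z[fallback, ] <- zm - rowMeans(zm)
  }
  list(z = z, fallback = fallback)
}

#' Pair origin- and target-organ samples by animal
#'
#' Cross-organ correlation treats the animal as the experimental unit: the
#' origin-organ sample and the target-organ sample of the same animal form
#' one paired observation. Returns the two expression matrices restricted to
#' animals with both organs, columns ordered identically by animal id.
#'
#' @param expr Expression matrix (genes x samples).
#' @param meta Sample metadata (see [read_metadata()]).
#' @param origin_organ,target_organ Organ names.
#' @return List with matrices `origin`, `target` (columns renamed to animal
#'   ids) and the vector `animals`.
#' @export
pair_by_animal <- function(expr, meta, origin_organ, target_organ) {
  meta <- validate_metadata(meta)
  mo <- meta |> filter(.data$organ == origin_organ, .data$sample_id %in% colnames(expr))
  mt <- meta |> filter(.data$organ == target_organ, .data$sample_id %in% colnames(expr))
  animals <- intersect(mo$animal_id, mt$animal_id)
  unmatched <- setdiff(union(mo$animal_id, mt$animal_id), animals)
  if (length(unmatched) > 0) {
    warn(paste0("animals without both organs dropped: ", paste(unmatched, collapse = ", ")))
  }
  if (length(animals) < 4) {
    abort(paste0("need >= 4 animals with both organs; unmatched: ",
                 paste(unmatched, collapse = ", ")), class = "interorgan_error")
  }
  animals <- sort(animals)
  so <- mo$sample_id[match(animals, mo$animal_id)]
  st <- mt$sample_id[match(animals, mt$animal_id)]
  origin <- expr[, so, drop = FALSE]
  target <- expr[, st, drop = FALSE]
  colnames(origin) <- colnames(target) <- animals
  list(origin = origin, target = target, animals = animals)
}
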