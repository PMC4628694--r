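#' Two-sided Wilcoxon rank-sum test
#'
#' Exact-distribution p-value (full enumeration of the rank-sum null)
#' when both groups have at most 10 observations and there are no
#' ties; otherwise the normal approximation with the tie-corrected
#' variance (no continuity correction). Two groups carrying identical
#' constant values give p = 1.
#'
#' @param values_s,values_ns Numeric vectors, both non-empty.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(values_s, values_ns) {
  if (!length(values_s) || !length(values_ns)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  pooled <- c(values_s, values_ns)
  if (length(unique(pooled)) == 1L) return(1)
  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && length(values_s) <= 10L && length(values_ns) <= 10L
  res <- suppressWarnings(
    wilcox.test(values_s, values_ns, alternative = "two.sided",
                exact = exact, correct = FALSE))
  p <- unname(res$p.value)
  if (is.na(p)) 1 else min(p, 1)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values: q_(i) = min over j >= i of
#' m * p_(j) / j, capped at 1, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Univariate survivor/nonsurvivor screen
#'
#' For every feature, compares the survivor and nonsurvivor
#' distributions with the two-sided Wilcoxon rank-sum test, reports
#' per-group median and quartiles (linear-interpolation quantiles),
#' Benjamini-Hochberg q-values, and flags significance at
#' `p < alpha`. Runs on the imputed matrix.
#'
#' @param matrix A [assemble_matrix()] result.
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @return Data frame with one row per feature (in matrix column
#'   order): `feature`, `median_S`, `q25_S`, `q75_S`, `median_NS`,
#'   `q25_NS`, `q75_NS`, `p_value`, `q_value`, `significant`.
#' @export
screen_features <- function(matrix, alpha = 0.05) {
  stopifnot(inherits(matrix, "cohort_matrix"), alpha > 0, alpha < 1)
  is_ns <- matrix$labels == "NS"
  if (!any(is_ns) || all(is_ns)) {
    stop("both survivor and nonsurvivor labels must be present",
         call. = FALSE)
  }
  x <- matrix$x
  qs <- function(v) quantile(v, c(0.25, 0.5, 0.75), names = FALSE,
                             type = 7)
  res <- lapply(seq_len(ncol(x)), function(j) {
    vs <- x[!is_ns, j]
    vn <- x[is_ns, j]
    a <- qs(vs); b <- qs(vn)
    data.frame(feature = matrix$feature_names[j],
               median_S = a[2], q25_S = a[1], q75_S = a[3],
               median_NS = b[2], q25_NS = b[1], q75_NS = b[3],
               p_value = rank_sum_test(vs, vn),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- fdr_adjust(out$p_value)
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}
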