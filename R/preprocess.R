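#' Filter genes by missingness
#'
#' Drops genes (rows) whose fraction of missing values exceeds
#' `max_missing_frac`, keeping the original row order.  This mirrors the
#' standard pre-filter applied before genome-wide liquid-association
#' analysis, where genes measured in too few conditions cannot support
#' stable within-tertile correlations.
#'
#' @param mat numeric matrix, genes x samples, with unique rownames (gene
#'   identifiers) and `NA` for missing values.
#' @param max_missing_frac maximum tolerated fraction of missing samples
#'   per gene, in `[0, 1]`.  Default 0.30.
#' @return the filtered matrix.  The number of removed genes is reported
#'   via [message()].
#' @export
#' @examples
#' m <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("g", 1:4), NULL))
#' m[1, 1:5] <- NA
#' filter_missing(m, 0.3)
filter_missing <- function(mat, max_missing_frac = 0.30) {
  mat <- .validate_expression(mat)
  stopifnot(is.numeric(max_missing_frac), length(max_missing_frac) == 1L,
            max_missing_frac >= 0, max_missing_frac <= 1)
  frac <- rowMeans(is.na(mat))
  keep <- frac <= max_missing_frac
  if (!any(keep)) {
    stop("no genes left after removing genes with more than ",
         format(100 * max_missing_frac), "% missing values", call. = FALSE)
  }
  if (any(!keep)) {
    message("filter_missing: removed ", sum(!keep), " of ", nrow(mat),
            " genes with > ", format(100 * max_missing_frac), "% missing")
  }
  mat[keep, , drop = FALSE]
}

#' Normal quantile transform
#'
#' Replaces the non-missing values of a vector by the standard-normal
#' quantiles of their ranks, `qnorm(rank / (n + 1))`, so the result is
#' marginally (approximately) standard normal while preserving the
#' ordering exactly.  Ties receive average ranks; missing values pass
#' through untouched.  The `rank/(n+1)` plotting position avoids infinite
#' quantiles at the extremes.
#'
#' @param x numeric vector, possibly with `NA`s; at least 3 non-missing
#'   values, not all identical.
#' @return numeric vector of the same length, `NA` where `x` is `NA`.
#' @export
#' @examples
#' normal_quantile_transform(c(5, 1, 3))   # median maps to 0
normal_quantile_transform <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 non-missing values", call. = FALSE)
  v <- x[ok]
  if (max(v) == min(v)) {
    stop("all non-missing values are identical; ranks are undefined",
         call. = FALSE)
  }
  out <- x
  out[ok] <- stats::qnorm(rank(v, ties.method = "average") / (n + 1))
  out
}

#' Standardize a vector to sample mean 0 and variance 1
#'
#' Centers and scales the non-missing values using the sample standard
#' deviation (denominator `n - 1`).  Missing values pass through.
#'
#' @param x numeric vector with at least 2 distinct non-missing values.
#' @return numeric vector with non-missing mean 0 and variance 1.
#' @export
standardize <- function(x) {
  ok <- !is.na(x)
  v <- x[ok]
  if (length(v) < 2L || max(v) == min(v)) {
    stop("standardize: need >= 2 distinct non-missing values", call. = FALSE)
  }
  out <- x
  out[ok] <- (v - mean(v)) / stats::sd(v)
  out
}

#' Preprocess an expression matrix for liquid-association analysis
#'
#' The full preprocessing pipeline: (1) remove genes with more than
#' `max_missing_frac` missing values, (2) per-gene normal quantile
#' transform, (3) per-gene standardization to mean 0, variance 1.  The
#' quantile transform makes each gene marginally normal (the conditional
#' normal model of stage two assumes normal margins) and damps outliers;
#' standardization after it is nearly a no-op but enforces exact sample
#' moments, on which the direct MLA estimator relies.
#'
#' @inheritParams filter_missing
#' @param transform if `FALSE`, skip the quantile-transform step and only
#'   filter + standardize.
#' @return preprocessed matrix of the same shape minus filtered genes.
#' @export
preprocess_expression <- function(mat, max_missing_frac = 0.30,
                                  transform = TRUE) {
  mat <- filter_missing(mat, max_missing_frac)
  out <- mat
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    if (transform) v <- normal_quantile_transform(v)
    out[i, ] <- standardize(v)
  }
  out
}

# Shared validation for the genes x samples container: numeric matrix,
# unique non-empty rownames.
.validate_expression <- function(mat) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("expression data must be a numeric genes x samples matrix",
         call. = FALSE)
  }
  ids <- rownames(mat)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("expression matrix must have gene identifiers as rownames",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  mat
}
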