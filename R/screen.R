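#' Equal-count binning of a numeric vector
#'
#' Splits the non-missing entries of `x` into `n_bins` contiguous groups
#' of (as nearly as possible) equal size by sorted value.  When the count
#' is not divisible by `n_bins`, the extra samples are assigned to the
#' outer bins first (lowest bin, then highest, working inwards), so the
#' middle bin is never larger than the outer ones.  Ties are broken by a
#' stable sort on (value, original index), making the split deterministic.
#'
#' @param x numeric vector, possibly with `NA`s.
#' @param n_bins number of bins (>= 2).
#' @return list of integer index vectors into `x`, lowest bin first.
#' @export
equal_count_bins <- function(x, n_bins = 3L) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2L)
  ok <- which(!is.na(x))
  n <- length(ok)
  if (n < n_bins) stop("fewer non-missing values than bins", call. = FALSE)
  ord <- ok[order(x[ok], ok, method = "radix")]
  sizes <- rep(n %/% n_bins, n_bins)
  rem <- n %% n_bins
  if (rem > 0L) {
    # outer-first preference order: 1, n_bins, 2, n_bins - 1, ...
    half <- ceiling(n_bins / 2)
    pref <- unique(as.vector(rbind(seq_len(half), n_bins + 1L - seq_len(half))))
    pref <- pref[pref >= 1L & pref <= n_bins]
    sizes[pref[seq_len(rem)]] <- sizes[pref[seq_len(rem)]] + 1L
  }
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-n_bins] + 1L)
  lapply(seq_len(n_bins), function(b) ord[starts[b]:ends[b]])
}

#' Tertile bins for a controller gene
#'
#' Assigns the samples with a non-missing controller value to
#' low/middle/high equal-count tertiles of controller expression, the
#' binning on which the `rho_diff` screen and the conditional-model
#' diagnostics are based.  Samples with a missing controller value are
#' excluded.  A controller with exactly two distinct values is treated as
#' a binary trait: the two groups become the low and high bins and the
#' middle bin is empty.
#'
#' Fewer than about 15 samples per bin gives unstable within-bin
#' correlations, so a warning (not an error) is raised in that case.
#'
#' @param x numeric vector of controller expression (possibly with `NA`s);
#'   at least 9 non-missing values unless binary.
#' @return an object of class `"bin_spec"`: list with integer index
#'   vectors `low_idx`, `mid_idx`, `high_idx`, the two cut values
#'   `boundaries`, the non-missing count `n`, and logical `binary`.
#' @export
tertile_bins <- function(x) {
  ok <- which(!is.na(x))
  n <- length(ok)
  vals <- unique(x[ok])
  if (length(vals) == 2L) {
    lo <- sort(vals)[1L]
    low <- ok[x[ok] == lo]
    high <- setdiff(ok, low)
    out <- list(low_idx = low, mid_idx = integer(0), high_idx = high,
                boundaries = sort(vals), n = n, binary = TRUE)
    class(out) <- "bin_spec"
    return(out)
  }
  if (n < 9L) {
    stop("need at least 9 non-missing controller values (3 per tertile), got ",
         n, call. = FALSE)
  }
  bins <- equal_count_bins(x, 3L)
  if (min(lengths(bins)) < 15L) {
    warning("a tertile has fewer than 15 samples (sizes ",
            paste(lengths(bins), collapse = "/"),
            "); within-bin correlations may be unstable", call. = FALSE)
  }
  out <- list(low_idx = bins[[1L]], mid_idx = bins[[2L]],
              high_idx = bins[[3L]],
              boundaries = c(max(x[bins[[1L]]]), min(x[bins[[3L]]])),
              n = n, binary = FALSE)
  class(out) <- "bin_spec"
  out
}

# Gene x gene Pearson correlation over the samples in `idx`, computed by
# cross-products of the row-standardized submatrix (one pass, no per-pair
# loop).  With missing values, rows are centered/scaled on their own
# observed entries, NAs set to 0, and cross-products normalized by
# pairwise-complete sums of squares -- exact Pearson when the bin is
# complete.  Rows with (near) zero variance in the bin come back as NA.
.bin_cor <- function(mat, idx, method = "pearson") {
  X <- mat[, idx, drop = FALSE]
  if (method == "spearman") {
    X <- t(apply(X, 1L, function(r) {
      out <- rep(NA_real_, length(r))
      ok <- !is.na(r)
      out[ok] <- rank(r[ok], ties.method = "average")
      out
    }))
  }
  obs <- !is.na(X)
  if (all(obs)) {
    Z <- X - rowMeans(X)
    ss <- rowSums(Z * Z)
    bad <- ss < 1e-24
    denom <- sqrt(outer(ss, ss))
    R <- tcrossprod(Z) / denom
    if (any(bad)) R[bad, ] <- R[, bad] <- NA_real_
    return(R)
  }
  cnt <- rowSums(obs)
  mu <- rowSums(X, na.rm = TRUE) / cnt
  Z <- X - mu
  Z[!obs] <- 0
  Z2 <- Z * Z
  ss_pair <- tcrossprod(Z2, obs * 1)    # (i, j): sum over s obs in j of z_i^2
  S <- tcrossprod(Z)
  R <- S / sqrt(ss_pair * t(ss_pair))
  bad <- rowSums(Z2) < 1e-24 | cnt < 3L
  if (any(bad)) R[bad, ] <- R[, bad] <- NA_real_
  R[!is.finite(R)] <- NA_real_
  R
}

#' Correlation-difference matrix for one controller
#'
#' For a fixed controller gene, computes the full gene-by-gene matrix of
#' `rho_diff = rho_high - rho_low`: the Pearson correlation of each gene
#' pair over the samples in the controller's top tertile minus the same
#' over the bottom tertile.  Both correlation matrices come from per-bin
#' cross-products of the re-standardized submatrix, which is what makes
#' the genome-wide screen fast.  The diagonal is 0 and the matrix is
#' symmetric; pairs with an undefined within-bin correlation (zero
#' variance inside a bin) are `NA` and their count is attached as
#' attribute `"n_undefined"`.
#'
#' @param mat preprocessed genes x samples matrix (see
#'   [preprocess_expression()]).
#' @param controller gene identifier (rowname of `mat`).
#' @param method `"pearson"` (default) or `"spearman"` (correlations on
#'   within-bin ranks, more robust to outliers).
#' @return symmetric numeric matrix of `rho_diff` values with attributes
#'   `"rho_high"`, `"rho_low"` (the two correlation matrices) and
#'   `"n_undefined"`.
#' @export
rho_diff_for_controller <- function(mat, controller,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  mat <- .validate_expression(mat)
  if (!controller %in% rownames(mat)) {
    stop("controller gene not in matrix: ", controller, call. = FALSE)
  }
  bins <- tertile_bins(mat[controller, ])
  Rh <- .bin_cor(mat, bins$high_idx, method)
  Rl <- .bin_cor(mat, bins$low_idx, method)
  D <- Rh - Rl
  diag(D) <- 0
  undef <- sum(is.na(D[upper.tri(D)]))
  if (undef > 0L) {
    message("rho_diff(", controller, "): ", undef,
            " gene pairs with undefined within-bin correlation")
  }
  structure(D, rho_high = Rh, rho_low = Rl, n_undefined = undef,
            binary = bins$binary)
}

#' Stage-one screen over all ordered triplets
#'
#' Iterates over every gene as controller, computes its `rho_diff` matrix
#' by per-bin cross-products, and emits each canonical triplet
#' (`x1 < x2` lexicographically, `x3` the controller, `x3` not in the
#' pair) with `|rho_diff| >= threshold`.  Only the per-controller matrix
#' is held in memory; hits are accumulated incrementally, so memory is
#' bounded by the hit count rather than the triplet space.
#'
#' @inheritParams rho_diff_for_controller
#' @param threshold screening cutoff on `|rho_diff|`, in `(0, 2]`.  The
#'   default 0.5 (25% of the attainable range) retains essentially all
#'   triplets with large liquid association while cutting the candidate
#'   space by roughly an order of magnitude.
#' @param controllers optional character vector restricting which genes
#'   are tried in the controller position (all genes by default).
#' @param verbose report per-controller progress via [message()].
#' @return data.frame with columns `x1`, `x2`, `x3`, `rho_high`,
#'   `rho_low`, `rho_diff`, one row per hit, plus a logical `binary`
#'   column marking binary-trait controllers.
#' @export
screen_all <- function(mat, threshold = 0.5,
                       method = c("pearson", "spearman"),
                       controllers = NULL, verbose = FALSE) {
  method <- match.arg(method)
  mat <- .validate_expression(mat)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 2)
  genes <- rownames(mat)
  if (is.null(controllers)) controllers <- genes
  stopifnot(all(controllers %in% genes))
  ut <- upper.tri(matrix(0, nrow(mat), nrow(mat)))
  pair_i <- row(ut)[ut]
  pair_j <- col(ut)[ut]
  out <- vector("list", length(controllers))
  for (k in seq_along(controllers)) {
    ctrl <- controllers[k]
    D <- rho_diff_for_controller(mat, ctrl, method)
    ci <- match(ctrl, genes)
    d <- D[ut]
    keep <- which(!is.na(d) & abs(d) >= threshold &
                    pair_i != ci & pair_j != ci)
    if (length(keep)) {
      i <- pair_i[keep]
      j <- pair_j[keep]
      g1 <- genes[i]
      g2 <- genes[j]
      swap <- g1 > g2
      tmp <- g1[swap]; g1[swap] <- g2[swap]; g2[swap] <- tmp
      Rh <- attr(D, "rho_high")
      Rl <- attr(D, "rho_low")
      out[[k]] <- data.frame(
        x1 = g1, x2 = g2, x3 = ctrl,
        rho_high = Rh[cbind(i, j)],
        rho_low = Rl[cbind(i, j)],
        rho_diff = d[keep],
        binary = attr(D, "binary"),
        stringsAsFactors = FALSE)
    }
    if (verbose) {
      message("screen: ", ctrl, " (", k, "/", length(controllers), "): ",
              length(keep), " hits")
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(x1 = character(0), x2 = character(0),
                      x3 = character(0), rho_high = numeric(0),
                      rho_low = numeric(0), rho_diff = numeric(0),
                      binary = logical(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Size of the ordered-triplet search space
#'
#' Number of ordered triplets (unordered gene pair, distinct controller)
#' among `G` genes: `G * (G - 1) * (G - 2) / 2`, i.e. `3 * choose(G, 3)`.
#' Returned as a double since genome-scale counts overflow 32-bit
#' integers (about 9.4e10 for ~5,700 genes).
#'
#' @param G number of genes (>= 3).
#' @return numeric count of candidate triplets.
#' @export
#' @examples
#' count_triplets(250)
count_triplets <- function(G) {
  stopifnot(is.numeric(G), length(G) == 1L, G == floor(G))
  if (G < 3) stop("need at least 3 genes to form a triplet", call. = FALSE)
  G <- as.double(G)
  G * (G - 1) * (G - 2) / 2
}
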