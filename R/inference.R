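#' Benjamini–Hochberg adjustment against a global test count
#'
#' Step-up false-discovery-rate adjustment where the divisor ranks refer
#' to positions within the supplied vector but the multiplier is a
#' *global* test count `n_tests`, which may far exceed the vector length.
#' This is the situation of a genome-wide triplet search: only the top
#' hits are carried forward, but the adjustment must account for every
#' triplet that entered model fitting (tens of millions), so
#' `p.adjust(..., n = n_tests)` semantics are required with the supplied
#' vector understood as the smallest `length(p)` of the `n_tests`
#' p-values.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @param n_tests total number of tests performed (`>= length(pvalues)`).
#' @return adjusted p-values, same order as the input; always
#'   `>= pvalues`, capped at 1, monotone in the step-up sense.
#' @export
#' @examples
#' bh_adjust(c(1e-6, 2e-3, 0.04), n_tests = 1000)
bh_adjust <- function(pvalues, n_tests = length(pvalues)) {
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  stopifnot(is.numeric(pvalues), all(is.finite(pvalues)),
            all(pvalues > 0), all(pvalues <= 1))
  if (n_tests < m) {
    stop("n_tests (", n_tests, ") is smaller than the number of p-values (",
         m, ")", call. = FALSE)
  }
  o <- order(pvalues)
  adj <- pmin(1, n_tests * pvalues[o] / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  adj[order(o)]
}

#' Run the full two-stage liquid-association pipeline
#'
#' Screens every ordered triplet with the tertile `rho_diff` statistic,
#' runs the estimation cascade (full CNM, simple CNM, robust bootstrap)
#' on each hit, adjusts p-values by Benjamini–Hochberg against the number
#' of triplets that entered estimation, and returns the result table
#' sorted by p-value (ties broken by `|MLA|` descending, then gene ids).
#'
#' All randomness (the robust fallback's bootstrap) derives from `seed`:
#' each hit gets a per-triplet seed from a deterministic sequence, so the
#' run is reproducible and a resumed run is identical to an uninterrupted
#' one.  With `checkpoint` set, per-triplet estimates are appended to
#' `<checkpoint>` and finished controllers recorded in
#' `<checkpoint>.done`; re-running with the same arguments skips the
#' finished controllers.
#'
#' Binary-trait controllers (exactly two distinct values) skip the model
#' stage entirely: for them `rho_diff` itself is the liquid-association
#' measure, reported with model code `"B"` and excluded from the BH pool.
#'
#' @inheritParams screen_all
#' @param seed integer master seed (required) for the bootstrap fallback.
#' @param n_bins bins for the direct estimator (default 3).
#' @param n_boot bootstrap replicates for the robust fallback.
#' @param bh_pool `"all"` pools every model-fitted triplet (F/S/R) into
#'   one adjustment; `"full_only"` adjusts only full-model p-values
#'   (others get `NA`), with the same global `n_tests`.
#' @param lof_corr_tol,lof_alpha,max_iter estimation tuning; see
#'   [estimate_triplet()].
#' @param checkpoint optional path for per-controller checkpointing.
#' @return data.frame of class `"fastla_result"` with columns `x1`, `x2`,
#'   `x3`, `rho_diff`, `mla`, `wald`, `pvalue`, `padj`, `model`.
#' @export
run_pipeline <- function(mat, threshold = 0.5, seed = 1L,
                         method = c("pearson", "spearman"), n_bins = 3L,
                         n_boot = 1000L, bh_pool = c("all", "full_only"),
                         lof_corr_tol = 0.35, lof_alpha = 0.01,
                         max_iter = 500L, checkpoint = NULL,
                         verbose = FALSE) {
  method <- match.arg(method)
  bh_pool <- match.arg(bh_pool)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  mat <- .validate_expression(mat)
  hits <- screen_all(mat, threshold = threshold, method = method,
                     verbose = verbose)
  empty <- data.frame(x1 = character(0), x2 = character(0),
                      x3 = character(0), rho_diff = numeric(0),
                      mla = numeric(0), wald = numeric(0),
                      pvalue = numeric(0), padj = numeric(0),
                      model = character(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) {
    class(empty) <- c("fastla_result", "data.frame")
    return(empty)
  }
  # stable global order: controllers in matrix order, hits as emitted
  hits$.idx <- seq_len(nrow(hits))
  done <- character(0)
  prev <- NULL
  if (!is.null(checkpoint) && file.exists(paste0(checkpoint, ".done"))) {
    done <- readLines(paste0(checkpoint, ".done"))
    if (file.exists(checkpoint)) {
      prev <- utils::read.delim(checkpoint, stringsAsFactors = FALSE)
      prev <- prev[prev$x3 %in% done, , drop = FALSE]
    } else {
      done <- character(0)
    }
  }
  rows <- list()
  for (ctrl in unique(hits$x3)) {
    if (ctrl %in% done) next
    sub <- hits[hits$x3 == ctrl, , drop = FALSE]
    ctrl_rows <- vector("list", nrow(sub))
    for (r in seq_len(nrow(sub))) {
      h <- sub[r, ]
      if (isTRUE(h$binary)) {
        ctrl_rows[[r]] <- data.frame(
          x1 = h$x1, x2 = h$x2, x3 = ctrl, rho_diff = h$rho_diff,
          mla = h$rho_diff, wald = NA_real_, pvalue = NA_real_,
          model = "B", stringsAsFactors = FALSE)
        next
      }
      trip_seed <- .triplet_seed(seed, h$.idx)
      est <- tryCatch(
        estimate_triplet(mat[h$x1, ], mat[h$x2, ], mat[ctrl, ],
                         n_bins = n_bins, n_boot = n_boot, seed = trip_seed,
                         lof_corr_tol = lof_corr_tol, lof_alpha = lof_alpha,
                         max_iter = max_iter),
        error = function(e) {
          stop("estimation failed for triplet (", h$x1, ", ", h$x2, " | ",
               ctrl, "): ", conditionMessage(e), call. = FALSE)
        })
      ctrl_rows[[r]] <- data.frame(
        x1 = h$x1, x2 = h$x2, x3 = ctrl, rho_diff = h$rho_diff,
        mla = est$mla, wald = est$wald, pvalue = est$pvalue,
        model = est$model, stringsAsFactors = FALSE)
    }
    block <- do.call(rbind, ctrl_rows)
    rows[[length(rows) + 1L]] <- block
    if (!is.null(checkpoint)) {
      utils::write.table(block, checkpoint, sep = "\t", quote = FALSE,
                         row.names = FALSE,
                         col.names = !file.exists(checkpoint),
                         append = file.exists(checkpoint))
      cat(ctrl, "\n", file = paste0(checkpoint, ".done"), append = TRUE)
    }
    if (verbose) message("estimate: ", ctrl, ": ", nrow(block), " triplets")
  }
  res <- do.call(rbind, c(list(prev), rows))
  if (is.null(res) || nrow(res) == 0L) {
    class(empty) <- c("fastla_result", "data.frame")
    return(empty)
  }
  tested <- res$model %in% c("F", "S", "R")
  res$padj <- NA_real_
  if (any(tested)) {
    n_tests <- sum(tested)
    pool <- if (bh_pool == "all") tested else tested & res$model == "F"
    if (any(pool)) res$padj[pool] <- bh_adjust(res$pvalue[pool], n_tests)
  }
  ord <- order(res$pvalue, -abs(res$mla), res$x1, res$x2, res$x3,
               na.last = TRUE)
  res <- res[ord, c("x1", "x2", "x3", "rho_diff", "mla", "wald",
                    "pvalue", "padj", "model")]
  rownames(res) <- NULL
  class(res) <- c("fastla_result", "data.frame")
  res
}

# Deterministic per-triplet seed stream: Lehmer step from the master seed
# and the hit's global index, kept inside 32-bit integer range.
.triplet_seed <- function(seed, idx) {
  as.integer((as.double(seed) * 48271 + as.double(idx) * 16807) %%
               2147483646) + 1L
}
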