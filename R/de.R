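# TPM normalization and differential-expression calling.

#' TPM-normalize a count matrix
#'
#' Small-RNA convention: reads per million mapped reads, with no length
#' normalization — `tpm(i, s) = count(i, s) / total(s) * 1e6`, so every
#' sample column sums to 1e6.
#'
#' @param counts An [expression_matrix()] of kind "count".
#' @return An `expression_matrix` of kind "tpm".
#' @examples
#' em <- expression_matrix(matrix(c(1, 3), 2, 1,
#'                         dimnames = list(c("a", "b"), "s1")), "BSB")
#' compute_tpm(em)$values
#' @export
compute_tpm <- function(counts) {
  stop_if(!inherits(counts, "expression_matrix"),
          "counts must be an expression_matrix")
  stop_if(counts$kind != "count", "compute_tpm expects raw counts")
  totals <- colSums(counts$values)
  bad <- totals == 0
  stop_if(any(bad), "sample(s) with zero total counts: %s",
          paste(colnames(counts$values)[bad], collapse = ", "))
  tpm <- sweep(counts$values, 2, totals, "/") * 1e6
  expression_matrix(tpm, counts$condition, kind = "tpm")
}

#' Differential-expression thresholds
#'
#' Defaults follow the conventional small-RNA DE screen: |log2 fold
#' change| > 1 and p < 0.05.
#'
#' @param min_abs_log2fc Minimum |log2FC| (strict inequality; >= 0).
#' @param max_p Maximum p-value (strict inequality; in (0, 1]).
#' @return Object of class `de_thresholds`.
#' @export
de_thresholds <- function(min_abs_log2fc = 1, max_p = 0.05) {
  stop_if(min_abs_log2fc < 0, "min_abs_log2fc must be >= 0")
  stop_if(max_p <= 0 || max_p > 1, "max_p must lie in (0, 1]")
  structure(list(min_abs_log2fc = min_abs_log2fc, max_p = max_p),
            class = "de_thresholds")
}

#' Two-condition differential-expression test on TPM values
#'
#' For every piRNA the fold change is
#' `log2fc = log2((mean BSB TPM + pseudo) / (mean NBS TPM + pseudo))`
#' (positive = higher in BSB) and the p-value comes from a two-sided
#' unequal-variance (Welch) two-sample t-test on `log2(TPM + pseudo)`.
#' When both groups have zero variance the test is degenerate: p = 1 if
#' the group means are equal, otherwise p is floored at 1e-12. Status is
#' `up` when `log2fc > min_abs_log2fc` and `p < max_p`, `down` when
#' `log2fc < -min_abs_log2fc` and `p < max_p`, else `ns`. No multiple-
#' testing correction is applied by default; `adjust = "BH"` switches the
#' status calls (and the reported `padj`) to Benjamini-Hochberg FDR.
#'
#' @param tpm An [expression_matrix()] of kind "tpm" with exactly the
#'   conditions "BSB" and "NBS" (>= 2 samples each).
#' @param thresholds A [de_thresholds()] object.
#' @param pseudo Pseudo-count in TPM units added before logs (default 1).
#' @param adjust "none" (default) or "BH".
#' @return data.frame of class `de_results` with columns id, log2fc, p
#'   (and padj when adjusted), status.
#' @export
de_test <- function(tpm, thresholds = de_thresholds(), pseudo = 1,
                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stop_if(!inherits(tpm, "expression_matrix"),
          "tpm must be an expression_matrix")
  stop_if(tpm$kind != "tpm", "de_test expects TPM values (run compute_tpm)")
  stop_if(!inherits(thresholds, "de_thresholds"),
          "thresholds must come from de_thresholds()")
  for (cond in c("BSB", "NBS")) {
    n <- sum(tpm$condition == cond)
    stop_if(n < 2L, "condition %s has %d sample(s); need >= 2", cond, n)
  }
  x <- log2(tpm$values[, tpm$condition == "BSB", drop = FALSE] + pseudo)
  y <- log2(tpm$values[, tpm$condition == "NBS", drop = FALSE] + pseudo)
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate & m1 == m2] <- 1
  p[degenerate & m1 != m2] <- 1e-12
  p <- pmax(p, 1e-12)

  mt_bsb <- rowMeans(tpm$values[, tpm$condition == "BSB", drop = FALSE])
  mt_nbs <- rowMeans(tpm$values[, tpm$condition == "NBS", drop = FALSE])
  log2fc <- log2((mt_bsb + pseudo) / (mt_nbs + pseudo))

  p_used <- p
  out <- data.frame(id = rownames(tpm$values), log2fc = log2fc, p = p,
                    stringsAsFactors = FALSE)
  if (adjust == "BH") {
    out$padj <- p.adjust(p, method = "BH")
    p_used <- out$padj
  }
  out$status <- ifelse(p_used < thresholds$max_p &
                         log2fc > thresholds$min_abs_log2fc, "up",
                ifelse(p_used < thresholds$max_p &
                         log2fc < -thresholds$min_abs_log2fc, "down", "ns"))
  rownames(out) <- NULL
  structure(out, class = c("de_results", "data.frame"),
            thresholds = thresholds, pseudo = pseudo, adjust = adjust)
}

#' Tally differential-expression calls
#'
#' @param results A [de_test()] result (or any data.frame with a `status`
#'   column).
#' @return Named numeric vector `c(n_total_de, n_up, n_down)` with
#'   `n_total_de = n_up + n_down`.
#' @export
de_counts <- function(results) {
  n_up <- sum(results$status == "up")
  n_down <- sum(results$status == "down")
  c(n_total_de = n_up + n_down, n_up = n_up, n_down = n_down)
}

#' @export
print.de_results <- function(x, ...) {
  th <- attr(x, "thresholds")
  n <- de_counts(x)
  cat(sprintf("DE screen on %d piRNAs (|log2FC| > %g, p < %g%s):\n",
              nrow(x), th$min_abs_log2fc, th$max_p,
              if (attr(x, "adjust") == "BH") ", BH-adjusted" else ""))
  cat(sprintf("  %d DE (%d up, %d down in BSB)\n",
              n[["n_total_de"]], n[["n_up"]], n[["n_down"]]))
  invisible(x)
}

#' @export
summary.de_results <- function(object, ...) {
  print(object)
  de <- object[object$status != "ns", , drop = FALSE]
  if (nrow(de) > 0L) {
    cat("  |log2FC| among DE calls: median",
        sprintf("%.2f, max %.2f\n", stats::median(abs(de$log2fc)),
                max(abs(de$log2fc))))
  }
  invisible(object)
}
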