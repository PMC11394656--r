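#' Construct an expression matrix with condition labels
#'
#' A thin container around a numeric piRNAs x samples matrix that carries
#' the per-sample condition labels and whether the values are raw counts or
#' TPM.
#'
#' @param values Numeric matrix, rows = piRNA ids, columns = sample ids.
#' @param condition Character/factor of per-sample condition labels (length
#'   = ncol(values)); names, if present, must match the column names.
#' @param kind "count" or "tpm".
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, condition, kind = c("count", "tpm")) {
  kind <- match.arg(kind)
  stop_if(!is.matrix(values) || !is.numeric(values),
          "values must be a numeric matrix")
  stop_if(any(values < 0), "expression values must be >= 0")
  if (kind == "count") {
    stop_if(any(values != round(values)), "counts must be integers")
  }
  stop_if(length(condition) != ncol(values),
          "condition must have one label per sample")
  if (!is.null(names(condition))) {
    stop_if(!identical(names(condition), colnames(values)),
            "condition names must match sample column names")
  }
  structure(list(values = values,
                 condition = setNames(as.character(condition),
                                      colnames(values)),
                 kind = kind),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix (%s): %d piRNAs x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  tb <- table(x$condition)
  cat("  conditions:",
      paste(sprintf("%s (n=%d)", names(tb), as.integer(tb)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a two-condition piRNA count matrix with known DE structure
#'
#' Per-piRNA baseline means are drawn log-normally around `nb_mean`
#' (mean-preserving, sdlog = 0.5) and counts are negative-binomial with
#' dispersion `nb_dispersion` (variance = mu + dispersion * mu^2). A
#' `de_fraction` of piRNAs carry a true condition effect: their mean is
#' multiplied by `2^effect_log2fc` in BSB (up, with probability
#' `de_up_share`) or in NBS (down).
#'
#' @param config A [generator_config()].
#' @param n_pirnas Number of piRNAs (rows).
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List with `counts` (an [expression_matrix()] of kind "count",
#'   samples BSB_1..n, NBS_1..n) and `truth` (data.frame id, de_status in
#'   up/down/ns, true_log2fc).
#' @examples
#' sim <- simulate_count_matrix(generator_config(), n_pirnas = 100, seed = 1)
#' table(sim$truth$de_status)
#' @export
simulate_count_matrix <- function(config, n_pirnas, seed = config$seed) {
  stop_if(!inherits(config, "generator_config"),
          "config must be a generator_config")
  stop_if(config$nb_dispersion <= 0, "nb_dispersion must be > 0")
  stop_if(config$n_replicates < 2, "need >= 2 replicates per condition")
  n_pirnas <- as.integer(n_pirnas)
  set.seed(as.integer(seed))

  nrep <- config$n_replicates
  sdlog <- 0.5
  base_mu <- rlnorm(n_pirnas, meanlog = log(config$nb_mean) - sdlog^2 / 2,
                    sdlog = sdlog)

  status <- rep("ns", n_pirnas)
  n_de <- as.integer(round(config$de_fraction * n_pirnas))
  if (n_de > 0L) {
    de_idx <- sample.int(n_pirnas, n_de)
    up <- runif(n_de) < config$de_up_share
    status[de_idx[up]] <- "up"
    status[de_idx[!up]] <- "down"
  }
  fc <- 2^config$effect_log2fc
  mu_bsb <- base_mu * ifelse(status == "up", fc, 1)
  mu_nbs <- base_mu * ifelse(status == "down", fc, 1)

  size <- 1 / config$nb_dispersion
  draw <- function(mu) {
    matrix(rnbinom(n_pirnas * nrep, mu = rep(mu, nrep), size = size),
           nrow = n_pirnas, ncol = nrep)
  }
  values <- cbind(draw(mu_bsb), draw(mu_nbs))
  ids <- sprintf("pi_%06d", seq_len(n_pirnas))
  rownames(values) <- ids
  colnames(values) <- c(sprintf("BSB_%d", seq_len(nrep)),
                        sprintf("NBS_%d", seq_len(nrep)))
  cond <- rep(c("BSB", "NBS"), each = nrep)
  list(counts = expression_matrix(values, cond, kind = "count"),
       truth = data.frame(id = ids, de_status = status,
                          true_log2fc = ifelse(status == "up",
                                               config$effect_log2fc,
                                        ifelse(status == "down",
                                               -config$effect_log2fc, 0)),
                          stringsAsFactors = FALSE))
}
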