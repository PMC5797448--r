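#' Co-expression strength of a correlation vector
#'
#' Difference between the 95th and 5th percentiles of the distribution of
#' pairwise clock-gene correlations (linear-interpolation percentile
#' definition, `stats::quantile` type 7). Large values mean gene pairs span
#' strong positive and strong negative correlations — the hallmark of a
#' progressing clock; values near 0 mean the pairs are uniformly weakly
#' correlated.
#'
#' @param cv A `cor_vector`, `ref_pattern`, or numeric vector of finite
#'   correlations.
#' @return Spread in \[0, 2\].
#' @examples
#' coexpression_strength(rep(0.3, 66))  # 0
#' @export
coexpression_strength <- function(cv) {
  rho <- pair_values(cv)
  if (anyNA(rho) || any(!is.finite(rho))) {
    stop("Correlations must all be finite.")
  }
  q <- stats::quantile(rho, c(0.05, 0.95), names = FALSE, type = 7)
  q[2L] - q[1L]
}

#' Median absolute deviation with Gaussian consistency constant
#'
#' median(|x - median(x)|) scaled by 1.4826, a robust alternative to the
#' standard deviation. The constant cancels in all MAD ratios.
#'
#' @param x Numeric vector with at least 2 finite values.
#' @return Nonnegative scale estimate (0 for constant input).
#' @examples
#' robust_mad(1:5)  # 1.4826
#' @export
robust_mad <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("MAD requires at least 2 finite values.")
  stats::mad(x, constant = 1.4826)
}

#' Differential expression variability between two conditions (MAD ratio)
#'
#' For each requested gene, computes the median absolute deviation of
#' expression within each condition and the log2 ratio
#' log2(MAD_a / MAD_b). With group a the perturbed condition (tumor,
#' knockout) and group b the control, negative values indicate reduced
#' expression variability in the perturbed condition — e.g. loss of the
#' rhythmic component of a clock gene.
#'
#' @inheritParams delta_ccd_test
#' @param genes Genes to summarise; default the clock signature panel.
#' @param log_transform If `TRUE`, values are transformed as log2(x + 1)
#'   before computing MADs (the usual convention for TPM-scale RNA-seq
#'   input); leave `FALSE` for values already on a log scale.
#' @return A data.frame with columns `gene`, `mad_a`, `mad_b`, and
#'   `log2_ratio` (NA when either MAD is zero, rather than +/-Inf).
#' @examples
#' sim <- simulate_clock(sim_config(n_samples = 40, n_background = 0,
#'                                  seed = 1))
#' lab <- rep(c("x", "y"), 20)
#' head(mad_log2_ratio(sim$expr, lab, group_a = "x", group_b = "y"))
#' @export
mad_log2_ratio <- function(expr, labels, genes = clock_signature()$gene,
                           group_a = NULL, group_b = NULL,
                           log_transform = FALSE, gene_map = NULL) {
  expr <- as_expression_matrix(expr)
  labels <- as.character(labels)
  if (length(labels) != ncol(expr)) {
    stop("`labels` must give one condition per sample column.")
  }
  levels <- unique(labels)
  if (is.null(group_a) != is.null(group_b)) {
    stop("Specify both group_a and group_b, or neither.")
  }
  if (is.null(group_a)) {
    if (length(levels) != 2L) {
      stop("Found ", length(levels),
           " condition levels; specify group_a and group_b.")
    }
    group_a <- levels[1L]
    group_b <- levels[2L]
  }
  if (!all(c(group_a, group_b) %in% levels)) {
    stop("group_a/group_b must be levels of `labels`.")
  }
  if (sum(labels == group_a) < 2L || sum(labels == group_b) < 2L) {
    stop("Each condition needs at least 2 samples for a MAD.")
  }
  idx <- match_genes(rownames(expr), genes, gene_map)
  if (anyNA(idx)) {
    stop("Gene(s) absent from expression data: ",
         paste(genes[is.na(idx)], collapse = ", "))
  }
  sub <- expr[idx, , drop = FALSE]
  if (log_transform) sub <- log2(sub + 1)

  mad_a <- apply(sub[, labels == group_a, drop = FALSE], 1L, robust_mad)
  mad_b <- apply(sub[, labels == group_b, drop = FALSE], 1L, robust_mad)
  ratio <- ifelse(mad_a > 0 & mad_b > 0, log2(mad_a / mad_b), NA_real_)
  data.frame(gene = genes, mad_a = unname(mad_a), mad_b = unname(mad_b),
             log2_ratio = unname(ratio), stringsAsFactors = FALSE)
}
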