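#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of average-ranked values (ties receive average ranks),
#' so the result is invariant to any strictly monotone transformation of
#' either input.
#'
#' @param x,y Numeric vectors of equal length, at least 3, neither constant.
#' @return Correlation in \[-1, 1\].
#' @examples
#' spearman(1:3, c(10, 20, 30))   #  1
#' spearman(1:4, c(1, 3, 2, 4))   #  0.8
#' @export
spearman <- function(x, y) {
  check_cor_input(x, y)
  stats::cor(rank(x), rank(y))
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation based on median-centered, MAD-scaled values with
#' Tukey biweights (tuning constant 9); weights are zero where the scaled
#' deviation reaches 1, so gross outliers are downweighted rather than
#' dominating as in Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length, at least 3; each must have a
#'   nonzero median absolute deviation.
#' @return Correlation in \[-1, 1\].
#' @examples
#' bicor(1:5, 5:1)  # -1
#' @export
bicor <- function(x, y) {
  check_cor_input(x, y)
  wx <- bicor_weights(x)
  wy <- bicor_weights(y)
  sum(wx * wy) / sqrt(sum(wx^2) * sum(wy^2))
}

# median-centered, biweight-downweighted deviations (tuning constant 9)
bicor_weights <- function(x) {
  med <- stats::median(x)
  s <- stats::mad(x, constant = 1)
  if (s == 0) {
    stop("Zero median absolute deviation: biweight midcorrelation undefined.")
  }
  u <- (x - med) / (9 * s)
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  (x - med) * w
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) {
    stop("Correlation inputs differ in length (", length(x), " vs ",
         length(y), ").")
  }
  if (length(x) < 3L) stop("Correlation requires at least 3 samples.")
  if (anyNA(x) || anyNA(y)) stop("Correlation inputs contain missing values.")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("Correlation undefined for a constant vector.")
  }
  invisible(TRUE)
}

#' Pairwise clock-gene correlation vector of a sample group
#'
#' Computes the correlation between every pair of signature genes across all
#' samples, returning the strict lower triangle of the correlation matrix as
#' a vector in the canonical pair order (see [signature_pairs()]). This
#' vector is the unit on which the clock correlation distance operates.
#'
#' @param expr Gene-by-sample numeric matrix (rownames are gene identifiers)
#'   or a data.frame with the gene identifier in the first column. Values may
#'   be on any monotone scale (log intensities, TPM, ...) for the rank-based
#'   method. Genes containing missing values are dropped with a warning.
#' @param signature Gene panel; default [clock_signature()].
#' @param method `"spearman"` (default) or `"bicor"`.
#' @param gene_map Optional two-column data.frame mapping identifiers found
#'   in `expr` to signature symbols (e.g. human orthologs onto the
#'   mouse-named panel). Matching is case-insensitive either way.
#' @param allow_subset If `TRUE`, signature genes absent from `expr` are
#'   dropped (with a warning) instead of raising an error. Any reference the
#'   resulting vector is compared against must be subset identically;
#'   [ccd()] enforces this by matching pair names.
#' @return An object of class `cor_vector`: list with `genes` (the signature
#'   genes used, in order), `rho` (named correlation vector, names
#'   `"gene1|gene2"`), `n_samples`, and `method`.
#' @examples
#' sim <- simulate_clock(sim_config(n_samples = 40, seed = 1))
#' cv <- correlation_vector(sim$expr)
#' length(cv$rho)  # 66
#' @export
correlation_vector <- function(expr, signature = clock_signature(),
                               method = c("spearman", "bicor"),
                               gene_map = NULL, allow_subset = FALSE) {
  method <- match.arg(method)
  signature <- as_signature(signature)
  expr <- drop_incomplete_genes(as_expression_matrix(expr))
  genes <- signature$gene

  idx <- match_genes(rownames(expr), genes, gene_map)
  if (anyNA(idx)) {
    missing <- genes[is.na(idx)]
    if (!allow_subset) {
      stop("Signature gene(s) absent from expression data: ",
           paste(missing, collapse = ", "),
           ". Use allow_subset = TRUE to restrict to the shared subset.")
    }
    warning("Restricting signature to ", sum(!is.na(idx)),
            " gene(s) present in the data; absent: ",
            paste(missing, collapse = ", "))
    genes <- genes[!is.na(idx)]
    idx <- idx[!is.na(idx)]
    if (length(genes) < 3L) stop("Fewer than 3 signature genes available.")
  }

  n <- ncol(expr)
  if (n < 3L) stop("At least 3 samples are required, got ", n, ".")
  if (n < 10L) {
    warning("Only ", n, " samples: correlation estimates will be unstable.")
  }

  sub <- expr[idx, , drop = FALSE]
  constant <- apply(sub, 1L, function(v) stats::var(v) == 0)
  if (any(constant)) {
    stop("Correlation undefined: constant expression for gene(s) ",
         paste(genes[constant], collapse = ", "))
  }

  cmat <- if (method == "spearman") {
    stats::cor(apply(sub, 1L, rank))
  } else {
    k <- length(genes)
    w <- apply(sub, 1L, bicor_weights)  # n x k columns of weighted deviations
    denom <- sqrt(colSums(w^2))
    crossprod(w) / tcrossprod(denom)
  }

  pairs <- signature_pairs(genes)
  rho <- cmat[cbind(match(pairs$gene1, genes), match(pairs$gene2, genes))]
  names(rho) <- paste(pairs$gene1, pairs$gene2, sep = "|")
  structure(list(genes = genes, rho = rho, n_samples = n, method = method),
            class = "cor_vector")
}

#' @export
print.cor_vector <- function(x, ...) {
  cat("Correlation vector (", x$method, "): ", length(x$genes), " genes, ",
      length(x$rho), " pairs, n = ", x$n_samples, " samples\n", sep = "")
  cat("  rho range [", round(min(x$rho), 3), ", ", round(max(x$rho), 3),
      "]\n", sep = "")
  invisible(x)
}

#' Square correlation matrix from a correlation vector
#'
#' Rebuilds the symmetric k-by-k matrix (unit diagonal) in signature order,
#' e.g. for heatmap export.
#'
#' @param cv A `cor_vector` or `ref_pattern`.
#' @return Numeric matrix with gene dimnames.
#' @export
cor_matrix <- function(cv) {
  genes <- cv$genes
  k <- length(genes)
  m <- diag(1, k)
  dimnames(m) <- list(genes, genes)
  pairs <- signature_pairs(genes)
  i <- match(pairs$gene1, genes)
  j <- match(pairs$gene2, genes)
  m[cbind(i, j)] <- cv$rho
  m[cbind(j, i)] <- cv$rho
  m
}
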