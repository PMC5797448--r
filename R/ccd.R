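#' Clock correlation distance between a test group and a reference
#'
#' Euclidean distance between two correlation vectors over the same ordered
#' gene pairs. A smaller CCD indicates greater similarity of clock gene
#' co-expression, i.e. a clock whose progression across samples resembles
#' the reference.
#'
#' @param test A `cor_vector` (or bare numeric vector of pair correlations).
#' @param reference A `ref_pattern`, `cor_vector`, or bare numeric vector of
#'   the same length and pair order.
#' @return Nonnegative distance.
#' @examples
#' ccd(rep(0.5, 66), rep(0.4, 66))  # 0.1 * sqrt(66)
#' @export
ccd <- function(test, reference) {
  a <- pair_values(test)
  b <- pair_values(reference)
  if (length(a) != length(b)) {
    stop("Correlation vectors differ in length (", length(a), " vs ",
         length(b), ").")
  }
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b))) {
    stop("Correlation vectors have mismatched gene-pair order.")
  }
  sqrt(sum((a - b)^2))
}

pair_values <- function(x) {
  if (inherits(x, "cor_vector") || inherits(x, "ref_pattern")) return(x$rho)
  if (is.numeric(x)) return(x)
  stop("Expected a cor_vector, ref_pattern, or numeric vector.")
}

#' Exact one-sided Monte Carlo permutation p-value
#'
#' (b + 1) / (m + 1) for b of m resampled null statistics at least as
#' extreme as the observed one. Counting the observed statistic among the
#' draws keeps the p-value positive (never below 1/(m+1)) and exact in the
#' permutation sense.
#'
#' @param b Count of null draws at least as extreme as observed (0..m).
#' @param m Number of null draws, at least 1.
#' @return p-value in (0, 1\].
#' @examples
#' exact_perm_p(0, 1000)  # 1/1001
#' @export
exact_perm_p <- function(b, m) {
  if (!is.numeric(b) || !is.numeric(m) || length(b) != 1L ||
      length(m) != 1L || m < 1 || b < 0 || b > m ||
      b != round(b) || m != round(m)) {
    stop("Require integer counts with 0 <= b <= m and m >= 1.")
  }
  (b + 1) / (m + 1)
}

#' Test whether clock co-expression is closer to the reference than chance
#'
#' Computes the observed CCD of the signature genes against the reference,
#' then estimates a null distribution by drawing 12 (in general, as many as
#' the signature has) genes uniformly without replacement from all measured
#' genes — clock genes included — `m` times. Each random gene set is
#' assigned to the reference's pair slots in draw order and its CCD is
#' computed against the same reference. The exact one-sided p-value is
#' (b + 1)/(m + 1) where b counts null CCDs less than or equal to the
#' observed one.
#'
#' @inheritParams correlation_vector
#' @param reference A `ref_pattern` for the same signature.
#' @param m Number of random gene sets (default 1000).
#' @param seed Integer seed; all randomness flows from it and the result is
#'   bit-reproducible.
#' @return Object of class `ccd_test`: list with `ccd`, `null_ccds`,
#'   `p_value`, `n_null`, `seed`, `n_samples`, and `method`.
#' @examples
#' ref <- default_reference()
#' sim <- simulate_clock(sim_config(n_samples = 40, n_background = 150,
#'                                  seed = 7))
#' res <- ccd_test(sim$expr, ref, m = 100, seed = 7)
#' res$p_value
#' @export
ccd_test <- function(expr, reference, signature = clock_signature(),
                     method = c("spearman", "bicor"), m = 1000L,
                     seed = 1L, gene_map = NULL) {
  method <- match.arg(method)
  if (!inherits(reference, c("ref_pattern", "cor_vector"))) {
    stop("`reference` must be a ref_pattern or cor_vector.")
  }
  if (m < 1) stop("`m` must be at least 1 (no null distribution otherwise).")
  expr <- drop_incomplete_genes(as_expression_matrix(expr))
  signature <- as_signature(signature)
  k <- length(signature$gene)

  if (nrow(expr) < k + 1L) {
    stop("Null resampling needs more measured genes (", nrow(expr),
         ") than signature genes (", k, ").")
  }
  if (nrow(expr) - k < 100L) {
    warning("Only ", nrow(expr) - k, " background genes: the random-gene ",
            "null distribution will be poorly resolved.")
  }

  obs_cv <- correlation_vector(expr, signature, method, gene_map = gene_map)
  observed <- ccd(obs_cv, reference)

  null_ccds <- with_seed(seed, {
    vapply(seq_len(m), function(i) {
      rows <- sample.int(nrow(expr), k)
      random_set_ccd(expr[rows, , drop = FALSE], reference, method)
    }, numeric(1))
  })

  b <- sum(null_ccds <= observed)
  structure(list(ccd = observed, null_ccds = null_ccds,
                 p_value = exact_perm_p(b, m), n_null = as.integer(m),
                 seed = as.integer(seed), n_samples = obs_cv$n_samples,
                 method = method),
            class = "ccd_test")
}

# CCD of an arbitrary k-gene submatrix whose rows fill the reference's pair
# slots in draw order. Constant rows (possible for random background genes)
# would make the correlation undefined; they are perturbed infinitesimally
# in rank space by treating their correlation as 0, matching the population
# value for an uninformative gene.
random_set_ccd <- function(sub, reference, method) {
  k <- nrow(sub)
  cmat <- if (method == "spearman") {
    suppressWarnings(stats::cor(apply(sub, 1L, rank)))
  } else {
    stats::cor(t(sub))  # placeholder, replaced below for bicor
  }
  if (method == "bicor") {
    w <- apply(sub, 1L, function(v) {
      tryCatch(bicor_weights(v), error = function(e) rep(0, length(v)))
    })
    denom <- sqrt(colSums(w^2))
    denom[denom == 0] <- Inf
    cmat <- crossprod(w) / tcrossprod(denom)
  }
  cmat[!is.finite(cmat)] <- 0
  idx <- utils::combn(k, 2L)
  rho <- cmat[cbind(idx[1L, ], idx[2L, ])]
  sqrt(sum((rho - unname(pair_values(reference)))^2))
}

#' @export
print.ccd_test <- function(x, ...) {
  cat("CCD test: CCD = ", signif(x$ccd, 4), ", p = ", signif(x$p_value, 4),
      " (", x$n_null, " random gene sets, n = ", x$n_samples,
      " samples, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Delta clock correlation distance between two conditions
#'
#' For two groups of samples (e.g. non-tumor and tumor) from one dataset,
#' computes each group's CCD against the same reference and reports the
#' difference delta = CCD(group b) - CCD(group a). A positive delta means
#' group b's clock co-expression is more perturbed than group a's. The null
#' distribution comes from `m` uniform random relabelings of the samples
#' preserving the two group sizes, always keeping the reference fixed; the
#' exact one-sided p-value counts permuted deltas greater than or equal to
#' the observed delta (alternative: group a is closer to the reference than
#' group b).
#'
#' @inheritParams ccd_test
#' @param labels Per-sample condition labels (character/factor), parallel to
#'   the columns of `expr`, with exactly two levels unless `group_a` and
#'   `group_b` select two of several.
#' @param group_a,group_b Which label is the control-like group a
#'   (e.g. non-tumor, wild-type) and which is group b (e.g. tumor,
#'   knockout). Defaults: the first and second level of `labels`.
#' @param m Number of label permutations (default 1000).
#' @return Object of class `delta_ccd_test`: list with `ccd_a`, `ccd_b`,
#'   `delta`, `null_deltas`, `p_value`, `n_null`, `seed`, `groups`, and
#'   `n_per_group`.
#' @examples
#' ref <- default_reference()
#' a <- simulate_clock(sim_config(n_samples = 30, n_background = 0, seed = 1))
#' b <- simulate_clock(sim_config(n_samples = 30, n_background = 0,
#'                                condition = "arrhythmic", seed = 2))
#' expr <- cbind(a$expr, b$expr)
#' colnames(expr) <- paste0("s", seq_len(ncol(expr)))
#' labels <- rep(c("wt", "ko"), each = 30)
#' res <- delta_ccd_test(expr, labels, ref, m = 200, seed = 3,
#'                       group_a = "wt", group_b = "ko")
#' res$delta
#' @export
delta_ccd_test <- function(expr, labels, reference,
                           signature = clock_signature(),
                           method = c("spearman", "bicor"), m = 1000L,
                           seed = 1L, group_a = NULL, group_b = NULL,
                           gene_map = NULL) {
  method <- match.arg(method)
  if (m < 1) stop("`m` must be at least 1.")
  expr <- drop_incomplete_genes(as_expression_matrix(expr))
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
      stop("Found ", length(levels), " condition levels; delta CCD compares ",
           "exactly two. Specify group_a/group_b or run pairwise.")
    }
    group_a <- levels[1L]
    group_b <- levels[2L]
  }
  if (!all(c(group_a, group_b) %in% levels)) {
    stop("group_a/group_b must be levels of `labels`.")
  }
  keep <- labels %in% c(group_a, group_b)
  expr <- expr[, keep, drop = FALSE]
  labels <- labels[keep]
  na <- sum(labels == group_a)
  nb <- sum(labels == group_b)
  if (na < 3L || nb < 3L) {
    stop("Each condition needs at least 3 samples (got ", na, " and ", nb,
         ").")
  }

  sig_idx <- match_genes(rownames(expr), as_signature(signature)$gene,
                         gene_map)
  if (anyNA(sig_idx)) {
    stop("Signature gene(s) absent from expression data: ",
         paste(as_signature(signature)$gene[is.na(sig_idx)], collapse = ", "))
  }
  sub <- expr[sig_idx, , drop = FALSE]
  rownames(sub) <- as_signature(signature)$gene
  ref_rho <- unname(pair_values(reference))
  is_a <- labels == group_a

  observed <- group_delta(sub, is_a, ref_rho, method)
  null_deltas <- with_seed(seed, {
    n <- length(is_a)
    vapply(seq_len(m), function(i) {
      perm <- logical(n)
      perm[sample.int(n, na)] <- TRUE
      unname(group_delta(sub, perm, ref_rho, method)["delta"])
    }, numeric(1))
  })

  b <- sum(null_deltas >= observed["delta"])
  structure(list(ccd_a = unname(observed["ccd_a"]),
                 ccd_b = unname(observed["ccd_b"]),
                 delta = unname(observed["delta"]),
                 null_deltas = null_deltas,
                 p_value = exact_perm_p(b, m), n_null = as.integer(m),
                 seed = as.integer(seed),
                 groups = c(a = group_a, b = group_b),
                 n_per_group = c(a = na, b = nb),
                 method = method),
            class = "delta_ccd_test")
}

# delta CCD for one assignment of samples to groups a (TRUE) / b (FALSE)
group_delta <- function(sub, is_a, ref_rho, method) {
  ca <- group_pair_cors(sub[, is_a, drop = FALSE], method)
  cb <- group_pair_cors(sub[, !is_a, drop = FALSE], method)
  ccd_a <- sqrt(sum((ca - ref_rho)^2))
  ccd_b <- sqrt(sum((cb - ref_rho)^2))
  c(ccd_a = ccd_a, ccd_b = ccd_b, delta = ccd_b - ccd_a)
}

group_pair_cors <- function(sub, method) {
  cmat <- if (method == "spearman") {
    suppressWarnings(stats::cor(apply(sub, 1L, rank)))
  } else {
    w <- apply(sub, 1L, bicor_weights)
    denom <- sqrt(colSums(w^2))
    crossprod(w) / tcrossprod(denom)
  }
  cmat[!is.finite(cmat)] <- 0
  k <- nrow(sub)
  idx <- utils::combn(k, 2L)
  cmat[cbind(idx[1L, ], idx[2L, ])]
}

#' @export
print.delta_ccd_test <- function(x, ...) {
  cat("Delta CCD test: CCD(", x$groups["a"], ") = ", signif(x$ccd_a, 4),
      ", CCD(", x$groups["b"], ") = ", signif(x$ccd_b, 4),
      ", delta = ", signif(x$delta, 4), ", p = ", signif(x$p_value, 4),
      " (", x$n_null, " permutations, n = ", x$n_per_group["a"], "+",
      x$n_per_group["b"], ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
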