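#' Fisher z-transformation of a correlation
#'
#' arctanh(r), approximately variance-stabilizing for correlation
#' coefficients. Values with |r| > 1 - 1e-6 are clipped to +/-(1 - 1e-6)
#' before transformation so that perfect correlations (possible at small
#' sample sizes) map to a large finite z rather than infinity.
#'
#' @param r Numeric vector of correlations in \[-1, 1\].
#' @return arctanh of the clipped values.
#' @examples
#' fisher_z(0)    # 0
#' fisher_z(0.5)  # 0.5493061
#' @export
fisher_z <- function(r) {
  if (!is.numeric(r) || anyNA(r) || any(!is.finite(r))) {
    stop("`r` must be finite correlation values.")
  }
  if (any(abs(r) > 1)) stop("Correlations must lie in [-1, 1].")
  eps <- 1e-6
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

#' Build a reference co-expression pattern by fixed-effects meta-analysis
#'
#' Combines per-dataset clock-gene correlation vectors into a single
#' reference pattern standing in for a normally progressing clock. For each
#' gene pair, the per-dataset correlations are Fisher z-transformed
#' (arctanh), averaged with weights n_i - 3 (the inverse variance of the
#' transformed correlation for dataset i with n_i samples), and mapped back
#' with tanh.
#'
#' @param cors List of `cor_vector` objects sharing one signature and pair
#'   order, one per dataset (e.g. from time-course data of healthy tissue).
#' @param n Optional numeric vector of per-dataset sample counts; defaults
#'   to the `n_samples` recorded in each correlation vector. Every count
#'   must be at least 4 so that the weight n - 3 is positive.
#' @return An object of class `ref_pattern`: list with `genes`, `rho`
#'   (meta-analyzed correlations, strictly inside (-1, 1), canonical pair
#'   order), and `contributing_n`.
#' @examples
#' panel <- simulate_reference_panel(3, n_samples = 24, seed = 1)
#' ref <- meta_reference(lapply(panel, function(d) correlation_vector(d$expr)))
#' range(ref$rho)
#' @export
meta_reference <- function(cors, n = NULL) {
  if (!is.list(cors) || length(cors) < 1L ||
      !all(vapply(cors, inherits, logical(1), "cor_vector"))) {
    stop("`cors` must be a non-empty list of cor_vector objects.")
  }
  genes <- cors[[1L]]$genes
  pair_names <- names(cors[[1L]]$rho)
  for (cv in cors[-1L]) {
    if (!identical(cv$genes, genes) || !identical(names(cv$rho), pair_names)) {
      stop("All correlation vectors must share one signature and pair order.")
    }
  }
  if (is.null(n)) n <- vapply(cors, function(cv) cv$n_samples, numeric(1))
  if (length(n) != length(cors)) {
    stop("`n` must give one sample count per dataset.")
  }
  if (any(n < 4)) {
    stop("Every dataset needs n >= 4 samples (meta-analysis weight n - 3).")
  }

  z <- vapply(cors, function(cv) fisher_z(cv$rho), numeric(length(pair_names)))
  z <- matrix(z, nrow = length(pair_names))
  w <- n - 3
  zbar <- as.vector(z %*% w) / sum(w)
  rho <- tanh(zbar)
  names(rho) <- pair_names
  structure(list(genes = genes, rho = rho, contributing_n = n),
            class = "ref_pattern")
}

#' @export
print.ref_pattern <- function(x, ...) {
  cat("Reference co-expression pattern: ", length(x$genes), " genes, ",
      length(x$rho), " pairs, meta-analyzed from ",
      length(x$contributing_n), " dataset(s) (total n = ",
      sum(x$contributing_n), ")\n", sep = "")
  invisible(x)
}

#' Built-in synthetic reference pattern
#'
#' A reference pattern for the 12-gene clock signature, meta-analyzed from
#' eight datasets produced by this package's own simulator (48 samples each,
#' noise SD 0.5, default phase architecture) with a fixed seed. It is
#' synthetic: it encodes the canonical two-arm phase structure of the
#' mammalian clock, not correlations estimated from real organ time courses.
#' Users with time-course data of healthy tissue should build their own
#' reference via [meta_reference()] and may ship it with [write_reference()].
#'
#' @return A `ref_pattern` object.
#' @examples
#' ref <- default_reference()
#' head(ref$rho)
#' @export
default_reference <- function() {
  path <- system.file("extdata", "reference_synthetic.csv",
                      package = "clockccd", mustWork = TRUE)
  read_reference(path)
}
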