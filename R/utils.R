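# internal helpers

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive k reproducible child seeds from one seed (kept below 2^31).
child_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Case-insensitive match of signature genes against matrix rownames, with an
# optional two-column mapping table (e.g. human symbols -> mouse signature).
# Returns integer row indices in signature order; NA where absent.
match_genes <- function(gene_ids, genes, gene_map = NULL) {
  ids <- toupper(gene_ids)
  if (!is.null(gene_map)) {
    stopifnot(is.data.frame(gene_map), ncol(gene_map) >= 2L)
    from <- toupper(as.character(gene_map[[1L]]))
    to <- toupper(as.character(gene_map[[2L]]))
    hit <- match(ids, from)
    ids[!is.na(hit)] <- to[hit[!is.na(hit)]]
  }
  match(toupper(genes), ids)
}

# Coerce expression input (matrix or data.frame with gene-id rownames /
# first column) to a numeric matrix with unique rownames and colnames.
as_expression_matrix <- function(expr) {
  if (is.data.frame(expr)) {
    if (!is.numeric(expr[[1L]]) && is.null(rownames(expr))) {
      rn <- as.character(expr[[1L]])
      expr <- as.matrix(expr[, -1L, drop = FALSE])
      rownames(expr) <- rn
    } else {
      expr <- as.matrix(expr)
    }
  }
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("Expression data must be a numeric gene-by-sample matrix.")
  }
  if (is.null(rownames(expr))) {
    stop("Expression matrix must have gene identifiers as rownames.")
  }
  if (anyDuplicated(rownames(expr))) {
    stop("Expression matrix has duplicated gene identifiers: ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))]),
               collapse = ", "))
  }
  if (!is.null(colnames(expr)) && anyDuplicated(colnames(expr))) {
    stop("Expression matrix has duplicated sample identifiers.")
  }
  expr
}

# Drop genes with any missing value, with a warning naming them.
drop_incomplete_genes <- function(expr) {
  bad <- rowSums(!is.finite(expr)) > 0L
  if (any(bad)) {
    warning("Dropping ", sum(bad), " gene(s) with missing/non-finite values: ",
            paste(utils::head(rownames(expr)[bad], 5L), collapse = ", "),
            if (sum(bad) > 5L) ", ..." else "")
    expr <- expr[!bad, , drop = FALSE]
  }
  expr
}
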