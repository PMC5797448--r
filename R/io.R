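#' Read a gene-by-sample expression matrix from delimited text
#'
#' Expects TSV or CSV (delimiter auto-detected) with gene identifiers in the
#' first column and a header row of sample identifiers. Duplicate gene
#' identifiers are collapsed by keeping the row with the largest variance
#' (with a warning); duplicate sample identifiers are an error.
#'
#' @param path Path to the file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  # fread silently uniquifies duplicate headers, so check the raw header line
  hdr <- strsplit(readLines(path, n = 1L), "[\t,;]")[[1L]]
  if (anyDuplicated(hdr[-1L])) {
    stop("Duplicate sample identifiers in '", basename(path), "': ",
         paste(unique(hdr[-1L][duplicated(hdr[-1L])]), collapse = ", "))
  }
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) stop("Expression file needs a gene column plus samples.")
  gene_ids <- as.character(dt[[1L]])
  vals <- dt[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                     !is.na(vals[[j]]))[1L]
      stop("Non-numeric value in '", basename(path), "' at row ",
           if (is.na(bad)) "?" else bad, ", column '", names(vals)[j], "'.")
    }
  }
  if (anyDuplicated(names(vals))) {
    stop("Duplicate sample identifiers in '", basename(path), "'.")
  }
  mat <- as.matrix(vals)
  rownames(mat) <- gene_ids

  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    warning("Collapsing ", length(dup), " duplicated gene identifier(s) by ",
            "keeping the max-variance row: ",
            paste(utils::head(dup, 5L), collapse = ", "))
    v <- apply(mat, 1L, stats::var)
    ord <- order(-v)  # max-variance row first, so !duplicated keeps it
    mat <- mat[ord, , drop = FALSE][!duplicated(gene_ids[ord]), , drop = FALSE]
    mat <- mat[order(match(rownames(mat), gene_ids)), , drop = FALSE]
  }
  mat
}

#' Write an expression matrix as TSV
#'
#' @param expr Gene-by-sample numeric matrix.
#' @param path Output path.
#' @param gene_col Name of the gene-identifier column. Default `"gene_id"`.
#' @export
write_expression <- function(expr, path, gene_col = "gene_id") {
  expr <- as_expression_matrix(expr)
  out <- data.table::data.table(gene = rownames(expr))
  data.table::setnames(out, "gene", gene_col)
  out <- cbind(out, data.table::as.data.table(expr))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a sample-to-condition label table
#'
#' Two-column delimited text: sample identifier, condition label. Returns a
#' named character vector (names are sample identifiers).
#'
#' @param path Path to the file.
#' @return Named character vector of condition labels.
#' @export
read_labels <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) stop("Label file needs sample_id and condition columns.")
  if (anyDuplicated(dt[[1L]])) stop("Duplicate sample identifiers in labels.")
  stats::setNames(as.character(dt[[2L]]), as.character(dt[[1L]]))
}

#' Write a sample-to-condition label table as TSV
#'
#' @param labels Named character vector (names are sample identifiers) or
#'   unnamed vector parallel to `sample_ids`.
#' @param path Output path.
#' @param sample_ids Sample identifiers if `labels` is unnamed.
#' @export
write_labels <- function(labels, path, sample_ids = names(labels)) {
  if (is.null(sample_ids)) stop("Sample identifiers are required.")
  data.table::fwrite(data.table::data.table(sample_id = sample_ids,
                                            condition = as.character(labels)),
                     path, sep = "\t")
  invisible(path)
}

#' Read a reference co-expression pattern from long-format CSV
#'
#' Expects columns `gene1`, `gene2`, `rho` with exactly one row per
#' unordered signature gene pair. Row order and within-pair gene order are
#' normalized to the canonical signature ordering on load, so any
#' permutation of a valid file reads identically.
#'
#' @param path Path to the CSV.
#' @param signature Gene panel fixing the canonical order; default
#'   [clock_signature()].
#' @return A `ref_pattern`.
#' @export
read_reference <- function(path, signature = clock_signature()) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("gene1", "gene2", "rho")
  if (!all(need %in% names(dt))) {
    stop("Reference file needs columns gene1, gene2, rho.")
  }
  signature <- as_signature(signature)
  genes <- signature$gene
  g1 <- genes[match(toupper(dt$gene1), toupper(genes))]
  g2 <- genes[match(toupper(dt$gene2), toupper(genes))]
  if (anyNA(g1) || anyNA(g2)) {
    stop("Reference file contains genes outside the signature: ",
         paste(unique(c(dt$gene1[is.na(g1)], dt$gene2[is.na(g2)])),
               collapse = ", "))
  }
  lo <- pmin(match(g1, genes), match(g2, genes))
  hi <- pmax(match(g1, genes), match(g2, genes))
  if (any(lo == hi)) stop("Reference file pairs a gene with itself.")
  key <- paste(genes[lo], genes[hi], sep = "|")
  pairs <- signature_pairs(genes)
  want <- paste(pairs$gene1, pairs$gene2, sep = "|")
  if (anyDuplicated(key) || length(key) != length(want) ||
      !setequal(key, want)) {
    stop("Reference file must contain each signature gene pair exactly once (",
         length(want), " pairs expected).")
  }
  rho <- as.numeric(dt$rho)[match(want, key)]
  if (anyNA(rho) || any(abs(rho) >= 1)) {
    stop("Reference correlations must be finite and strictly inside (-1, 1).")
  }
  names(rho) <- want
  structure(list(genes = genes, rho = rho, contributing_n = NA_real_),
            class = "ref_pattern")
}

#' Write a reference pattern as long-format CSV
#'
#' Columns `gene1`, `gene2`, `rho`, one row per canonical pair — the
#' package's interchange format for references.
#'
#' @param ref A `ref_pattern` (or `cor_vector`).
#' @param path Output path.
#' @export
write_reference <- function(ref, path) {
  pairs <- signature_pairs(ref$genes)
  data.table::fwrite(data.table::data.table(gene1 = pairs$gene1,
                                            gene2 = pairs$gene2,
                                            rho = unname(ref$rho)),
                     path)
  invisible(path)
}

#' Write a square correlation matrix as CSV (heatmap export)
#'
#' @param cv A `cor_vector` or `ref_pattern`.
#' @param path Output path.
#' @export
write_cor_matrix <- function(cv, path) {
  m <- cor_matrix(cv)
  out <- data.table::data.table(gene = rownames(m))
  out <- cbind(out, data.table::as.data.table(m))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' Emits the expression TSV, a condition label TSV (all samples labelled
#' with the simulated condition), and a truth JSON (times, phases,
#' amplitudes, baselines, seed) sufficient to audit the simulation.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix. Default `"sim"`.
#' @return Invisibly, the paths written.
#' @export
write_sim_dataset <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expr = file.path(dir, paste0(prefix, "_expr.tsv")),
    labels = file.path(dir, paste0(prefix, "_labels.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.json"))
  )
  write_expression(sim$expr, paths["expr"])
  write_labels(rep(sim$config$condition, ncol(sim$expr)), paths["labels"],
               sample_ids = colnames(sim$expr))
  truth <- c(sim$truth,
             list(condition = sim$config$condition, seed = sim$config$seed,
                  noise_sd = sim$config$noise_sd))
  jsonlite::write_json(truth, paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
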