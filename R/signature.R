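#' The 12-gene circadian clock signature
#'
#' The panel of core clock and clock-controlled genes whose pairwise
#' co-expression defines the clock correlation distance. Gene order is
#' canonical and fixes the ordering of every correlation vector produced by
#' the package. Each gene carries an arm annotation: the positive arm
#' (Arntl, Npas2, Clock) peaks shortly before zeitgeber time 0, the negative
#' arms (Cry2, Nr1d1, Nr1d2, Per1, Per2, Per3, Dbp, Tef) peak near ZT10, and
#' Cry1 sits between the two, peaking near ZT18.
#'
#' @return A data.frame with columns `gene` (character, 12 symbols in
#'   canonical order) and `arm` (one of `"positive"`, `"intermediate"`,
#'   `"negative"`), of class `clock_signature`.
#' @examples
#' sig <- clock_signature()
#' sig$gene
#' table(sig$arm)
#' @export
clock_signature <- function() {
  sig <- data.frame(
    gene = c("Arntl", "Npas2", "Clock", "Cry1", "Cry2", "Nr1d1",
             "Nr1d2", "Per1", "Per2", "Per3", "Dbp", "Tef"),
    arm = c("positive", "positive", "positive", "intermediate",
            rep("negative", 8L)),
    stringsAsFactors = FALSE
  )
  class(sig) <- c("clock_signature", "data.frame")
  sig
}

#' Validate a gene signature
#'
#' Custom signatures (any ordered panel of at least 3 distinct genes) are
#' allowed wherever a signature is accepted; the default is the 12-gene
#' clock panel. A plain character vector is promoted to a signature with
#' unannotated arms.
#'
#' @param sig A `clock_signature` data.frame or a character vector of gene
#'   symbols.
#' @return A validated `clock_signature` data.frame.
#' @keywords internal
as_signature <- function(sig) {
  if (is.character(sig)) {
    sig <- data.frame(gene = sig, arm = NA_character_,
                      stringsAsFactors = FALSE)
    class(sig) <- c("clock_signature", "data.frame")
  }
  stopifnot(is.data.frame(sig), "gene" %in% names(sig))
  genes <- as.character(sig$gene)
  if (length(genes) < 3L) {
    stop("A signature needs at least 3 genes, got ", length(genes), ".")
  }
  if (anyDuplicated(genes)) {
    stop("Signature genes must be distinct; duplicated: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  sig
}

#' Canonical gene-pair ordering for a signature
#'
#' Enumerates index pairs (i, j) with i < j lexicographically in signature
#' order: (1,2), (1,3), ..., (1,k), (2,3), ..., (k-1,k). This is the strict
#' lower (equivalently upper) triangle of the correlation matrix, and every
#' correlation vector in the package uses this order.
#'
#' @param genes Character vector of gene symbols in signature order.
#' @return A data.frame with columns `gene1`, `gene2`, one row per pair.
#' @examples
#' nrow(signature_pairs(clock_signature()$gene))  # 66
#' @export
signature_pairs <- function(genes) {
  genes <- as_signature(genes)$gene
  idx <- utils::combn(seq_along(genes), 2L)
  data.frame(gene1 = genes[idx[1L, ]], gene2 = genes[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Number of unordered pairs among k items
#'
#' k(k-1)/2: 12 signature genes give 66 gene pairs; 8 reference datasets
#' give 28 pairwise distances.
#'
#' @param k Integer count of items, at least 2.
#' @return Integer pair count.
#' @examples
#' pair_count(12)  # 66
#' pair_count(8)   # 28
#' @export
pair_count <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 2 ||
      k != round(k)) {
    stop("`k` must be a single integer >= 2.")
  }
  as.integer(k * (k - 1) / 2)
}
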