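# TPM conversion and KO presence/adjudication.

#' Convert raw gene counts to TPM
#'
#' Per sample: `TPM_i = (c_i / L_i) / sum_j (c_j / L_j) * 1e6`. Lengths enter
#' in bp; the kilobase conversion cancels in the ratio, so no x1000 factor is
#' applied (and a test pins this down). Samples with zero total count keep an
#' all-zero row and raise a warning.
#'
#' @param counts Numeric samples x genes matrix (rownames = samples,
#'   colnames = genes).
#' @param lengths Named numeric vector `gene_id -> length_bp`; must cover
#'   every gene in `counts` with length >= 1.
#' @param layer Optional layer tag ("metagenome" or "metatranscriptome"),
#'   stored as an attribute.
#' @return Numeric samples x genes matrix of TPM with attribute `layer`; every
#'   row with any nonzero count sums to 1e6 (relative tolerance 1e-9).
#' @export
compute_tpm <- function(counts, lengths, layer = NULL) {
  stopifnot(is.matrix(counts), !is.null(colnames(counts)))
  missing <- setdiff(colnames(counts), names(lengths))
  if (length(missing) > 0L) {
    stop(sprintf(
      "compute_tpm: no length for gene '%s'", missing[1L]
    ), call. = FALSE)
  }
  L <- lengths[colnames(counts)]
  if (any(L < 1)) {
    stop(sprintf(
      "compute_tpm: length < 1 bp for gene '%s'",
      colnames(counts)[which(L < 1)[1L]]
    ), call. = FALSE)
  }
  rate <- sweep(counts, 2L, L, "/")
  tot <- rowSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning(sprintf(
      "compute_tpm: all-zero sample(s): %s",
      paste(rownames(counts)[zero], collapse = ", ")
    ), call. = FALSE)
    tot[zero] <- 1  # keeps the row all-zero
  }
  tpm <- rate / tot * 1e6
  attr(tpm, "layer") <- layer
  tpm
}

#' Adjudicate KOfam hits to one KO per gene
#'
#' Keeps rows with `score > threshold` and `evalue < 1e-5`, then picks one KO
#' per gene: best score, ties broken by lowest e-value, then lexicographically
#' smallest KO id.
#'
#' @param rows A data.frame as from [read_kofam()].
#' @param max_evalue E-value cutoff (default 1e-5).
#' @return Named character vector `gene_id -> KO`.
#' @export
filter_kofam <- function(rows, max_evalue = 1e-5) {
  dt <- data.table::as.data.table(rows)
  dt <- dt[score > threshold & evalue < max_evalue]
  if (nrow(dt) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  data.table::setorder(dt, gene_id, -score, evalue, ko_id)
  best <- dt[, .SD[1L], by = gene_id]
  stats::setNames(best$ko_id, best$gene_id)
}

#' KOs present in each sample (genes with TPM > 0)
#'
#' A KO is present in a sample iff at least one gene in `scope` carries it
#' with TPM strictly greater than zero.
#'
#' @param tpm TPM matrix (samples x genes).
#' @param annotations Named character vector `gene_id -> KO`.
#' @param scope Optional character vector of gene ids restricting the scan
#'   (e.g. the genes of one family); default all genes of `tpm`.
#' @param pooled If TRUE return a single KO vector pooled over all samples
#'   (present in any sample) instead of a per-sample list.
#' @return Named list `sample -> character vector of KOs`, or a single vector
#'   when `pooled = TRUE`.
#' @export
present_kos <- function(tpm, annotations, scope = NULL, pooled = FALSE) {
  genes <- colnames(tpm)
  if (!is.null(scope)) {
    extra <- setdiff(scope, genes)
    if (length(extra) > 0L) {
      stop(sprintf(
        "present_kos: scope gene '%s' not in the TPM matrix", extra[1L]
      ), call. = FALSE)
    }
    genes <- intersect(genes, scope)
  }
  genes <- genes[genes %in% names(annotations)]
  ko <- annotations[genes]
  keep <- !is.na(ko) & nzchar(ko)
  genes <- genes[keep]
  ko <- ko[keep]
  if (pooled) {
    any_pos <- colSums(tpm[, genes, drop = FALSE] > 0) > 0
    return(sort(unique(unname(ko[any_pos]))))
  }
  out <- lapply(rownames(tpm), function(s) {
    sort(unique(unname(ko[tpm[s, genes] > 0])))
  })
  stats::setNames(out, rownames(tpm))
}
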