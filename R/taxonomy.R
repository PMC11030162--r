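# Best-bit-score taxonomy and taxon-level TPM aggregation.
#
# Lineages are data.tables with a gene_id column plus the ordered rank columns
# superkingdom..genus (see split_lineage()); a truncated lineage has NA in a
# suffix of ranks, never a gap. Reporting stops at family level: the rank
# floor of metagenomic best-hit assignment.

#' Assign each gene the lineage of its best BLAST hit
#'
#' Per query gene the hit with the maximal bitscore wins; ties are broken by
#' lower e-value, then lexicographically smaller `subject_id` (BLAST output
#' order is not stable across runs, so the tie-break makes assignment
#' deterministic). Subjects absent from `taxmap` contribute an unassigned
#' lineage (with one warning); genes listed in `genes` but without hits are
#' unassigned.
#'
#' @param hits A data.frame of hits as from [read_blast6()].
#' @param taxmap A data.frame with `subject_id` plus rank columns
#'   (see [read_taxmap()]).
#' @param genes Optional character vector of all gene ids; genes without any
#'   hit get an all-`NA` (unassigned) lineage row.
#' @return A `data.table` with `gene_id` plus the rank columns.
#' @export
assign_best_hit <- function(hits, taxmap, genes = NULL) {
  hits <- data.table::as.data.table(hits)
  taxmap <- data.table::as.data.table(taxmap)
  if (nrow(hits) > 0L) {
    uncovered <- setdiff(unique(hits$subject_id), taxmap$subject_id)
    if (length(uncovered) > 0L) {
      warning(sprintf(
        "assign_best_hit: %d subject(s) missing from taxmap (e.g. '%s'); treated as unassigned",
        length(uncovered), uncovered[1L]
      ), call. = FALSE)
    }
    data.table::setorder(hits, query_id, -bitscore, evalue, subject_id)
    best <- hits[, .SD[1L], by = query_id]
    lin <- merge(
      best[, .(gene_id = query_id, subject_id)],
      taxmap, by = "subject_id", all.x = TRUE, sort = FALSE
    )[, c("gene_id", LINEAGE_RANKS), with = FALSE]
  } else {
    lin <- data.table::data.table(gene_id = character(0))
    for (r in LINEAGE_RANKS) {
      data.table::set(lin, j = r, value = character(0))
    }
  }
  if (!is.null(genes)) {
    miss <- setdiff(genes, lin$gene_id)
    if (length(miss) > 0L) {
      pad <- data.table::data.table(gene_id = miss)
      for (r in LINEAGE_RANKS) {
        data.table::set(pad, j = r, value = NA_character_)
      }
      lin <- rbind(lin, pad)
    }
    lin <- lin[match(genes, gene_id)]
  }
  data.table::setorder(lin, gene_id)
  lin[]
}

#' Aggregate TPM into a taxon profile at a given rank
#'
#' TPM is summed per taxon label at `rank`. Genes whose lineage is truncated
#' above `rank` roll up to `"unclassified <nearest present higher rank>"`;
#' genes with no lineage at all (or absent from `lineages`) go to
#' `"unassigned"`. Mass is conserved: per-sample sums equal the sample's total
#' TPM.
#'
#' @param tpm TPM matrix (samples x genes).
#' @param lineages A data.frame with `gene_id` plus rank columns.
#' @param rank One of superkingdom, phylum, class, order, family. Requesting
#'   genus (below the reporting floor) is an error.
#' @return Long-format `data.table`: `sample`, `taxon`, `tpm`.
#' @export
aggregate_by_rank <- function(tpm, lineages, rank = "family") {
  allowed <- setdiff(LINEAGE_RANKS, "genus")
  if (!rank %in% allowed) {
    stop(sprintf(
      "aggregate_by_rank: rank '%s' below the family-level reporting floor",
      rank
    ), call. = FALSE)
  }
  lin <- data.table::as.data.table(lineages)
  labels <- taxon_labels(lin, rank)
  gene_label <- stats::setNames(labels, lin$gene_id)
  lab <- gene_label[colnames(tpm)]
  lab[is.na(lab)] <- "unassigned"
  res <- data.table::data.table(
    sample = rep(rownames(tpm), times = ncol(tpm)),
    taxon = rep(unname(lab), each = nrow(tpm)),
    tpm = as.vector(tpm)
  )
  out <- res[, .(tpm = sum(tpm)), by = .(sample, taxon)]
  data.table::setorder(out, sample, -tpm, taxon)
  out[]
}

# label of each lineage row at `rank`, with unclassified/unassigned roll-up
taxon_labels <- function(lin, rank) {
  idx <- match(rank, LINEAGE_RANKS)
  lab <- lin[[rank]]
  need_roll <- is.na(lab)
  if (any(need_roll) && idx > 1L) {
    higher <- as.matrix(lin[need_roll, LINEAGE_RANKS[seq_len(idx - 1L)],
                            with = FALSE])
    rolled <- apply(higher, 1L, function(r) {
      pres <- which(!is.na(r))
      if (length(pres) == 0L) "unassigned"
      else paste("unclassified", r[max(pres)])
    })
    lab[need_roll] <- rolled
  } else {
    lab[need_roll] <- "unassigned"
  }
  lab
}

#' Merge low-abundance taxa into a "Below 1%" category
#'
#' A taxon is merged when its share of the *total* profile mass (all samples
#' pooled, pseudo-categories included in the denominator) is below
#' `threshold`. The `"unassigned"` pseudo-category is never merged; mass is
#' conserved exactly.
#'
#' @param profile Long-format profile (`sample`, `taxon`, `tpm`) as from
#'   [aggregate_by_rank()]; any extra grouping columns are preserved.
#' @param threshold Fraction of total mass (default 0.01).
#' @param taxon_col Name of the column holding the labels to merge
#'   (default `"taxon"`).
#' @return Profile of the same shape with merged rows relabelled
#'   `"Below 1%"` and re-summed.
#' @export
group_below_threshold <- function(profile, threshold = 0.01,
                                  taxon_col = "taxon") {
  stopifnot(threshold > 0, threshold < 1)
  dt <- data.table::copy(data.table::as.data.table(profile))
  tot <- sum(dt$tpm)
  if (tot == 0) return(dt)
  taxon_tot <- dt[, .(mass = sum(tpm)), by = taxon_col]
  low <- taxon_tot[[taxon_col]][taxon_tot$mass / tot < threshold]
  low <- setdiff(low, "unassigned")
  if (length(low) == 0L) return(dt)
  dt[get(taxon_col) %in% low, (taxon_col) := "Below 1%"]
  keys <- setdiff(names(dt), "tpm")
  out <- dt[, .(tpm = sum(tpm)), by = keys]
  data.table::setorderv(out, intersect(c("sample", keys), names(out)))
  out[]
}

#' Per-sample family richness and group medians
#'
#' Counts, for each sample, the distinct real family labels among genes with
#' TPM > 0. `"unassigned"` and truncated (`unclassified *`) lineages are
#' excluded from the count.
#'
#' @param tpm TPM matrix (samples x genes).
#' @param lineages A data.frame with `gene_id` plus rank columns.
#' @param groups Optional named character vector `sample -> group`; when
#'   given, medians per group are reported (standard midpoint rule).
#' @return A list with `per_sample` (named integer vector) and
#'   `group_medians` (named numeric vector, or NULL).
#' @export
family_richness <- function(tpm, lineages, groups = NULL) {
  lin <- data.table::as.data.table(lineages)
  fam <- stats::setNames(lin$family, lin$gene_id)
  fam <- fam[colnames(tpm)]
  per_sample <- vapply(rownames(tpm), function(s) {
    f <- fam[tpm[s, ] > 0]
    length(unique(f[!is.na(f)]))
  }, integer(1))
  medians <- NULL
  if (!is.null(groups)) {
    g <- groups[names(per_sample)]
    medians <- vapply(
      split(per_sample, g), stats::median, numeric(1)
    )
  }
  list(per_sample = per_sample, group_medians = medians)
}
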