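# CAZyme substrate-target profiling: dbCAN family -> substrate target,
# focal vs non-focal origin split, taxon-group aggregation.

#' Load a CAZy-family to substrate-target map
#'
#' Reads a two-column TSV (`cazy_family`, `target`). With `path = NULL` the
#' packaged default map is used (a curated mapping shipped as an editable
#' resource; the md5 of the file in use is attached as attribute `checksum`
#' so reports are auditable against the exact mapping).
#'
#' @param path Optional path to a custom map.
#' @return Named character vector `cazy_family -> target` with attribute
#'   `checksum`.
#' @export
load_substrate_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "substrate_map.tsv", package = "fbmeta")
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("cazy_family", "target") %in% names(dt))) {
    stop("load_substrate_map: expected columns cazy_family, target",
         call. = FALSE)
  }
  if (anyDuplicated(dt$cazy_family)) {
    stop("load_substrate_map: duplicate cazy_family rows", call. = FALSE)
  }
  smap <- stats::setNames(dt$target, dt$cazy_family)
  attr(smap, "checksum") <- unname(tools::md5sum(path))
  smap
}

#' Map CAZy families to substrate targets
#'
#' Subfamily suffixes (e.g. `GH5_5`) fall back to the base family when the
#' exact label is unmapped; families absent from the map resolve to
#' `"unknown"`.
#'
#' @param cazy_families Character vector of family labels, or a list of such
#'   vectors (one per gene).
#' @param smap Map from [load_substrate_map()].
#' @return Same shape as the input with targets substituted; for list input
#'   each element is the gene's *distinct* target set.
#' @export
map_substrates <- function(cazy_families, smap) {
  lookup <- function(f) {
    hit <- smap[f]
    base <- sub("_.*$", "", f)
    hit[is.na(hit)] <- smap[base[is.na(hit)]]
    hit[is.na(hit)] <- "unknown"
    unname(hit)
  }
  if (is.list(cazy_families)) {
    return(lapply(cazy_families, function(f) unique(lookup(f))))
  }
  lookup(cazy_families)
}

#' Build a CAZyme target profile split by origin and taxon group
#'
#' Restricts to genes carrying at least one CAZy family, maps families to
#' substrate targets, and aggregates TPM by (sample, origin, taxon group,
#' target). A gene with several distinct targets has its TPM divided equally
#' among them, so mass is conserved: per sample, the profile sums to that
#' sample's total CAZyme-gene TPM. Origin is `"focal"` iff the gene's
#' best-hit lineage matches the focal taxon.
#'
#' @param tpm TPM matrix (samples x genes).
#' @param dbcan A data.frame (`gene_id`, `cazy_family`) as from
#'   [read_dbcan()].
#' @param lineages A data.frame with `gene_id` plus rank columns.
#' @param focal Focal-taxon specifier, see [parse_focal()].
#' @param rank Taxon grouping rank: superkingdom, phylum or family
#'   (default "phylum").
#' @param smap Substrate map; default the packaged one.
#' @param below_threshold If non-NULL, merge targets (and taxa) whose share of
#'   the total profile mass is below this fraction into `"Below 1%"`
#'   (default 0.01; set NULL to skip).
#' @return Long-format `data.table`: `sample`, `origin`, `taxon`, `target`,
#'   `tpm`, with the substrate-map checksum as attribute `smap_checksum`.
#' @export
build_profile <- function(tpm, dbcan, lineages, focal, rank = "phylum",
                          smap = load_substrate_map(),
                          below_threshold = 0.01) {
  if (!rank %in% c("superkingdom", "phylum", "family")) {
    stop("build_profile: rank must be superkingdom, phylum or family",
         call. = FALSE)
  }
  dbcan <- data.table::as.data.table(dbcan)
  lin <- data.table::as.data.table(lineages)
  focal_spec <- parse_focal(focal)
  # focal gene set (errors if the focal taxon is absent entirely)
  fs <- focal_share(tpm, lin, focal_spec)  # validates resolvability
  rm(fs)
  if (is.null(names(focal_spec))) {
    is_focal <- rowSums(
      as.matrix(lin[, LINEAGE_RANKS, with = FALSE]) == focal_spec,
      na.rm = TRUE
    ) > 0
  } else {
    is_focal <- rep(TRUE, nrow(lin))
    for (r in names(focal_spec)) {
      is_focal <- is_focal & !is.na(lin[[r]]) & lin[[r]] == focal_spec[[r]]
    }
  }
  origin_map <- stats::setNames(
    ifelse(is_focal, "focal", "non-focal"), lin$gene_id
  )
  taxon_map <- stats::setNames(taxon_labels(lin, rank), lin$gene_id)

  caz_genes <- intersect(unique(dbcan$gene_id), colnames(tpm))
  if (length(caz_genes) == 0L) {
    out <- data.table::data.table(
      sample = character(0), origin = character(0), taxon = character(0),
      target = character(0), tpm = numeric(0)
    )
    data.table::setattr(out, "smap_checksum", attr(smap, "checksum"))
    return(out)
  }
  # distinct targets per gene and the equal-split weight
  gt <- unique(data.table::data.table(
    gene_id = dbcan$gene_id,
    target = map_substrates(dbcan$cazy_family, smap)
  ))[gene_id %in% caz_genes]
  gt[, w := 1 / .N, by = gene_id]
  gt[, origin := ifelse(is.na(origin_map[gene_id]), "non-focal",
                        origin_map[gene_id])]
  gt[, taxon := ifelse(is.na(taxon_map[gene_id]), "unassigned",
                       taxon_map[gene_id])]

  long <- data.table::data.table(
    sample = rep(rownames(tpm), times = length(caz_genes)),
    gene_id = rep(caz_genes, each = nrow(tpm)),
    tpm = as.vector(tpm[, caz_genes, drop = FALSE])
  )
  merged <- merge(long, gt, by = "gene_id", allow.cartesian = TRUE)
  merged[, tpm := tpm * w]
  out <- merged[, .(tpm = sum(tpm)), by = .(sample, origin, taxon, target)]
  if (!is.null(below_threshold)) {
    out <- group_below_threshold(out, below_threshold, taxon_col = "target")
    out <- group_below_threshold(out, below_threshold, taxon_col = "taxon")
  }
  data.table::setorder(out, sample, origin, taxon, target)
  data.table::setattr(out, "smap_checksum", attr(smap, "checksum"))
  out[]
}

#' Normalize a CAZyme profile to per-sample shares
#'
#' Each cell is divided by its sample's total CAZyme TPM, so rows of the
#' share column sum to 1 per sample. Samples with zero CAZyme TPM are dropped
#' with a warning. Shares are over CAZyme TPM only (not total sample TPM);
#' this denominator choice is recorded as attribute `denominator`.
#'
#' @param profile Long-format profile from [build_profile()].
#' @return The profile with an added `share` column.
#' @export
target_share_table <- function(profile) {
  dt <- data.table::copy(data.table::as.data.table(profile))
  if (nrow(dt) == 0L) {
    stop("target_share_table: empty profile", call. = FALSE)
  }
  dt[, total := sum(tpm), by = sample]
  zero <- unique(dt$sample[dt$total == 0])
  if (length(zero) > 0L) {
    warning(sprintf(
      "target_share_table: zero CAZyme TPM in sample(s): %s",
      paste(zero, collapse = ", ")
    ), call. = FALSE)
    dt <- dt[total > 0]
  }
  dt[, share := tpm / total]
  dt[, total := NULL]
  data.table::setattr(dt, "denominator", "sample-CAZyme-TPM")
  dt[]
}
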