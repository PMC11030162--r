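# Sample decay-status confirmation: Euclidean distances, PCA, Ward.D2
# clustering with feature-bootstrap support, and the retain/reassign/rescue
# decision rule.

#' Euclidean distance matrix between samples
#'
#' @param tpm TPM matrix (samples x genes), at least 2 samples.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(tpm) {
  if (nrow(tpm) < 2L) {
    stop("distance_matrix: need at least 2 samples", call. = FALSE)
  }
  as.matrix(stats::dist(tpm, method = "euclidean"))
}

#' PCA of the sample x gene TPM matrix
#'
#' Column-centered singular value decomposition (no scaling). Component signs
#' are fixed so that each loading vector's largest-magnitude entry is
#' positive, making score signs reproducible across BLAS implementations.
#'
#' @param tpm TPM matrix (samples x genes), at least 2 samples.
#' @param n_components Number of components to return (default 2, capped at
#'   the matrix rank).
#' @return A list with `scores` (samples x components),
#'   `explained_variance` (fractions, one per returned component) and
#'   `rotation`.
#' @export
pca_profile <- function(tpm, n_components = 2L) {
  if (nrow(tpm) < 2L) {
    stop("pca_profile: need at least 2 samples", call. = FALSE)
  }
  p <- stats::prcomp(tpm, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$rotation))
  for (j in seq_len(k)) {
    load <- p$rotation[, j]
    if (load[which.max(abs(load))] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  var_frac <- p$sdev^2 / sum(p$sdev^2)
  list(
    scores = p$x[, seq_len(k), drop = FALSE],
    explained_variance = var_frac[seq_len(k)],
    rotation = p$rotation[, seq_len(k), drop = FALSE]
  )
}

#' Ward.D2 hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with the Ward criterion on unsquared Euclidean
#' distances (the `ward.D2` convention: the update rule squares distances
#' internally). Merge order is deterministic for a given matrix.
#'
#' @param dist_m Symmetric distance matrix as from [distance_matrix()].
#' @param k Number of flat clusters to cut (default 2: healthy vs rotten).
#' @return A list with `hclust` (the dendrogram) and `clusters`
#'   (named integer vector of flat memberships at `k`).
#' @export
ward_cluster <- function(dist_m, k = 2L) {
  hc <- stats::hclust(stats::as.dist(dist_m), method = "ward.D2")
  clusters <- stats::cutree(hc, k = min(k, nrow(dist_m)))
  list(hclust = hc, clusters = clusters)
}

# leaf-label sets of every internal node, in merge order (last = root)
cluster_leafsets <- function(hc) {
  n_merge <- nrow(hc$merge)
  sets <- vector("list", n_merge)
  for (i in seq_len(n_merge)) {
    m <- hc$merge[i, ]
    left <- if (m[1L] < 0L) hc$labels[-m[1L]] else sets[[m[1L]]]
    right <- if (m[2L] < 0L) hc$labels[-m[2L]] else sets[[m[2L]]]
    sets[[i]] <- sort(c(left, right))
  }
  sets
}

#' Bootstrap support of the Ward.D2 clusters
#'
#' Each iteration resamples gene columns with replacement, recomputes the
#' Euclidean distance matrix and the Ward.D2 dendrogram, and scores each
#' internal cluster of the original dendrogram 1 if its exact leaf set occurs
#' among the bootstrap tree's internal-node leaf sets. Columns are sorted by
#' gene id before resampling, so support is invariant to gene-column
#' permutation of the input for a fixed seed.
#'
#' @param tpm TPM matrix (samples x genes).
#' @param iterations Number of bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @return A `data.table` with one row per internal cluster of the original
#'   dendrogram: `members` (comma-joined sorted sample ids), `n_members`,
#'   `support` in `[0,1]`; the original `hclust` object is attached as
#'   attribute `"hclust"`.
#' @export
bootstrap_support <- function(tpm, iterations = 1000L, seed = 1L) {
  stopifnot(iterations >= 1L)
  tpm <- tpm[, order(colnames(tpm)), drop = FALSE]
  hc <- ward_cluster(distance_matrix(tpm))$hclust
  orig <- cluster_leafsets(hc)
  keys <- vapply(orig, paste, character(1), collapse = "\r")
  hits <- integer(length(keys))
  set.seed(seed)
  for (b in seq_len(iterations)) {
    idx <- sample.int(ncol(tpm), replace = TRUE)
    bt <- stats::hclust(stats::dist(tpm[, idx, drop = FALSE]),
                        method = "ward.D2")
    bkeys <- vapply(cluster_leafsets(bt), paste, character(1),
                    collapse = "\r")
    hits <- hits + as.integer(keys %in% bkeys)
  }
  out <- data.table::data.table(
    members = vapply(orig, paste, character(1), collapse = ","),
    n_members = lengths(orig),
    support = hits / iterations
  )
  data.table::setattr(out, "hclust", hc)
  out[]
}

#' Parse a focal-taxon specifier
#'
#' Accepts a named character vector of rank = label constraints
#' (e.g. `c(family = "Polyporaceae", genus = "Fomes")`), or a string
#' `"Family:Genus"` (two fields), or a single bare label matched against any
#' rank.
#'
#' @param focal The specifier.
#' @return Named character vector of rank constraints, or an unnamed
#'   single label (any-rank match).
#' @export
parse_focal <- function(focal) {
  if (!is.null(names(focal))) {
    bad <- setdiff(names(focal), LINEAGE_RANKS)
    if (length(bad) > 0L) {
      stop(sprintf("parse_focal: unknown rank '%s'", bad[1L]), call. = FALSE)
    }
    return(focal)
  }
  stopifnot(is.character(focal), length(focal) == 1L)
  parts <- strsplit(focal, ":", fixed = TRUE)[[1L]]
  if (length(parts) == 2L) {
    return(c(family = parts[1L], genus = parts[2L]))
  }
  focal
}

#' Per-sample TPM share of the focal taxon
#'
#' @param tpm TPM matrix (samples x genes).
#' @param lineages A data.frame with `gene_id` plus rank columns.
#' @param focal Focal-taxon specifier, see [parse_focal()].
#' @return Named numeric vector of fractions in `[0,1]`.
#' @export
focal_share <- function(tpm, lineages, focal) {
  lin <- data.table::as.data.table(lineages)
  focal <- parse_focal(focal)
  if (is.null(names(focal))) {
    is_focal <- rowSums(
      as.matrix(lin[, LINEAGE_RANKS, with = FALSE]) == focal, na.rm = TRUE
    ) > 0
  } else {
    is_focal <- rep(TRUE, nrow(lin))
    for (r in names(focal)) {
      is_focal <- is_focal & !is.na(lin[[r]]) & lin[[r]] == focal[[r]]
    }
  }
  if (!any(is_focal)) {
    stop("focal_share: focal taxon absent from all lineages", call. = FALSE)
  }
  focal_genes <- intersect(lin$gene_id[is_focal], colnames(tpm))
  tot <- rowSums(tpm)
  share <- rowSums(tpm[, focal_genes, drop = FALSE]) / ifelse(tot == 0, 1, tot)
  stats::setNames(share, rownames(tpm))
}

#' Confirm or reassign sample decay status
#'
#' Combines the metagenomic Ward.D2 cluster structure with focal-taxon TPM
#' shares in both omic layers:
#' \enumerate{
#'   \item Samples whose total metatranscriptome reads fall below `min_reads`
#'     are excluded from MT-based evidence (`mt_excluded`).
#'   \item A sample with an intermediate metagenomic focal share
#'     (`mg_low <= share < mg_high`) is assigned healthy iff its MT focal
#'     share reaches `mt_rescue` (tag `rescued_by_MT`), otherwise rotten;
#'     with no usable MT layer the tag is `excluded_low_reads`.
#'   \item All other samples take the majority putative label of their k = 2
#'     cluster (tag `retained` when it matches the field label,
#'     `reassigned_by_cluster` otherwise). A within-cluster majority tie is
#'     broken toward healthy for the cluster with the higher mean MG focal
#'     share.
#' }
#'
#' @param mg_tpm Metagenome TPM matrix (samples x genes).
#' @param mt_tpm Metatranscriptome TPM matrix; samples may be a subset.
#' @param lineages A data.frame with `gene_id` plus rank columns.
#' @param focal Focal-taxon specifier, see [parse_focal()].
#' @param putative Named character vector `sample -> "healthy"|"rotten"`.
#' @param mt_read_counts Optional named numeric vector of total MT reads per
#'   sample (drives the `min_reads` exclusion).
#' @param mg_low,mg_high Bounds of the intermediate MG focal-share band
#'   (defaults 0.01 and 0.50).
#' @param mt_rescue MT focal share at or above which an intermediate sample is
#'   rescued as healthy (default 0.10).
#' @param min_reads MT library-size floor (default 3500).
#' @param iterations,seed Bootstrap iterations and seed for cluster support.
#' @return A list with `report` (a `data.table`: sample, putative_status,
#'   cluster, cluster_support, mg_focal_share, mt_focal_share, mt_excluded,
#'   PC1, PC2, final_status, rationale), `distances`, `pca`, `hclust`, and
#'   the full `support` table.
#' @export
classify_samples <- function(mg_tpm, mt_tpm, lineages, focal, putative,
                             mt_read_counts = NULL,
                             mg_low = 0.01, mg_high = 0.50,
                             mt_rescue = 0.10, min_reads = 3500,
                             iterations = 1000L, seed = 1L) {
  samples <- rownames(mg_tpm)
  stopifnot(all(samples %in% names(putative)))
  mg_share <- focal_share(mg_tpm, lineages, focal)
  mt_share <- stats::setNames(rep(NA_real_, length(samples)), samples)
  common <- intersect(samples, rownames(mt_tpm))
  if (length(common) > 0L) {
    mt_share[common] <- focal_share(
      mt_tpm[common, , drop = FALSE], lineages, focal
    )
  }
  mt_excluded <- is.na(mt_share)
  if (!is.null(mt_read_counts)) {
    low <- names(mt_read_counts)[mt_read_counts < min_reads]
    mt_excluded[intersect(samples, low)] <- TRUE
  }

  dist_m <- distance_matrix(mg_tpm)
  cl <- ward_cluster(dist_m, k = 2L)
  support <- bootstrap_support(mg_tpm, iterations = iterations, seed = seed)
  pca <- pca_profile(mg_tpm)

  # majority putative label per cluster; tie -> higher mean MG focal share
  # cluster is healthy
  clusters <- cl$clusters[samples]
  cluster_label <- vapply(sort(unique(clusters)), function(cid) {
    members <- samples[clusters == cid]
    n_h <- sum(putative[members] == "healthy")
    n_r <- sum(putative[members] == "rotten")
    if (n_h > n_r) return("healthy")
    if (n_r > n_h) return("rotten")
    means <- vapply(sort(unique(clusters)), function(c2) {
      mean(mg_share[samples[clusters == c2]])
    }, numeric(1))
    if (means[cid] == max(means)) "healthy" else "rotten"
  }, character(1))
  names(cluster_label) <- as.character(sort(unique(clusters)))

  # support of each sample's k=2 cluster (singletons trivially 1)
  support_key <- stats::setNames(support$support, support$members)
  cluster_support <- vapply(samples, function(s) {
    members <- paste(sort(samples[clusters == clusters[s]]), collapse = ",")
    if (!members %in% names(support_key)) 1 else support_key[[members]]
  }, numeric(1))

  final <- character(length(samples))
  rationale <- character(length(samples))
  names(final) <- names(rationale) <- samples
  for (s in samples) {
    share <- mg_share[s]
    if (share >= mg_low && share < mg_high) {
      if (!mt_excluded[s] && mt_share[s] >= mt_rescue) {
        final[s] <- "healthy"
        rationale[s] <- "rescued_by_MT"
      } else {
        final[s] <- "rotten"
        rationale[s] <- if (mt_excluded[s]) "excluded_low_reads"
          else if (putative[s] == "rotten") "retained"
          else "reassigned_by_cluster"
      }
    } else {
      final[s] <- cluster_label[[as.character(clusters[s])]]
      rationale[s] <- if (final[s] == putative[s]) "retained"
        else "reassigned_by_cluster"
    }
  }

  report <- data.table::data.table(
    sample = samples,
    putative_status = unname(putative[samples]),
    cluster = unname(clusters),
    cluster_support = unname(cluster_support),
    mg_focal_share = unname(mg_share),
    mt_focal_share = unname(mt_share[samples]),
    mt_excluded = unname(mt_excluded[samples]),
    PC1 = unname(pca$scores[samples, 1L]),
    PC2 = if (ncol(pca$scores) >= 2L) unname(pca$scores[samples, 2L])
          else NA_real_,
    final_status = unname(final),
    rationale = unname(rationale)
  )
  list(report = report, distances = dist_m, pca = pca,
       hclust = cl$hclust, clusters = clusters, support = support)
}
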