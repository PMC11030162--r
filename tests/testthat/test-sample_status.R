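test_that("distance_matrix is Euclidean, symmetric, permutation-invariant", {
  tpm <- tiny_tpm(rbind(c(1e6, 0), c(0, 1e6), c(1e6, 0)))
  d <- distance_matrix(tpm)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d, t(d))
  expect_equal(d["S1", "S2"], sqrt(2) * 1e6)
  expect_equal(d["S1", "S3"], 0)
  expect_error(distance_matrix(tpm[1, , drop = FALSE]), "at least 2")

  set.seed(4)
  m <- tiny_tpm(matrix(runif(60), nrow = 6))
  perm <- sample(colnames(m))
  expect_equal(distance_matrix(m), distance_matrix(m[, perm]))
})

test_that("distances satisfy the triangle inequality on random inputs", {
  set.seed(14)
  for (i in 1:25) {
    m <- tiny_tpm(matrix(runif(40, 0, 1e5), nrow = 4))
    d <- distance_matrix(m)
    for (a in 1:4) for (b in 1:4) for (c in 1:4) {
      expect_lte(d[a, b], d[a, c] + d[c, b] + 1e-6)
    }
  }
})

test_that("pca_profile fixes signs and reports explained variance", {
  # rank-1 data: one component explains everything
  base <- c(1, 2, 3, 4)
  tpm <- tiny_tpm(outer(c(1, 2, 3), base))
  p <- pca_profile(tpm)
  expect_equal(p$explained_variance[1], 1)
  # sign convention: the largest-magnitude loading is positive
  expect_gt(p$rotation[which.max(abs(p$rotation[, 1])), 1], 0)

  # duplicated identical samples collapse to equal scores
  dup <- tiny_tpm(rbind(c(5, 5), c(5, 5), c(1, 9)))
  pd <- pca_profile(dup)
  expect_equal(pd$scores[1, ], pd$scores[2, ])
  expect_lte(sum(pd$explained_variance), 1 + 1e-12)
})

test_that("ward_cluster merges coincident points first, heights monotone", {
  tpm <- tiny_tpm(rbind(c(0, 0), c(0, 0), c(100, 100)))
  wc <- ward_cluster(distance_matrix(tpm))
  expect_equal(wc$hclust$height[1], 0)
  first_pair <- sort(-wc$hclust$merge[1, ])
  expect_equal(first_pair, c(1, 2))  # the coincident pair
  expect_equal(unname(wc$clusters[1]), unname(wc$clusters[2]))
  expect_false(wc$clusters[1] == wc$clusters[3])

  set.seed(31)
  m <- tiny_tpm(matrix(runif(80, 0, 1e4), nrow = 8))
  h <- ward_cluster(distance_matrix(m))$hclust$height
  expect_true(all(diff(h) >= -1e-9))
})

test_that("ward k=2 recovers planted conditions on a default community", {
  ds <- small_dataset(seed = 2, depth = 5e4)
  tpm <- compute_tpm(ds$mg_counts, gene_lengths(ds$annotations))
  cl <- ward_cluster(distance_matrix(tpm))$clusters
  cond <- ds$truth$condition
  expect_equal(length(unique(cl[cond == "healthy"])), 1L)
  expect_equal(length(unique(cl[cond == "rotten"])), 1L)
  expect_false(cl[cond == "healthy"][1] == cl[cond == "rotten"][1])
})

test_that("bootstrap_support scores exact leaf-set recurrence", {
  # a duplicated pair survives any column resample
  tpm <- tiny_tpm(rbind(c(1, 1, 1), c(1, 1, 1), c(9, 9, 9), c(5, 0, 5)),
                  samples = c("A", "B", "C", "D"))
  bs <- bootstrap_support(tpm, iterations = 50, seed = 3)
  expect_equal(bs[members == "A,B"]$support, 1.0)
  # iterations = 1 gives Bernoulli supports
  b1 <- bootstrap_support(tpm, iterations = 1, seed = 3)
  expect_true(all(b1$support %in% c(0, 1)))
  # root always recurs
  expect_equal(bs[n_members == 4]$support, 1.0)
})

test_that("bootstrap_support is invariant to gene-column permutation", {
  set.seed(6)
  tpm <- tiny_tpm(matrix(runif(60, 0, 1e4), nrow = 6))
  perm <- sample(colnames(tpm))
  a <- bootstrap_support(tpm, iterations = 40, seed = 9)
  b <- bootstrap_support(tpm[, perm], iterations = 40, seed = 9)
  expect_equal(a$support, b$support)
  expect_equal(a$members, b$members)
})

test_that("classify_samples applies retain/reassign/rescue/exclude rules", {
  ds <- small_dataset(seed = 17, n_healthy = 4, n_rotten = 4, depth = 3e4)
  ds <- make_transitional(ds, "R03", 0.05, 0.60, seed = 5)
  ds <- make_transitional(ds, "R04", 0.05, 0.01, seed = 6)
  lens <- gene_lengths(ds$annotations)
  lin <- lineage_cols(ds$annotations)
  mg <- compute_tpm(ds$mg_counts, lens)
  mt <- compute_tpm(ds$mt_counts, lens)
  putative <- c(H01 = "healthy", H02 = "healthy", H03 = "healthy",
                H04 = "rotten",   # mislabeled in the field
                R01 = "rotten", R02 = "rotten",
                R03 = "rotten", R04 = "rotten")
  res <- classify_samples(mg, mt, lin, "Polyporaceae:Fomes", putative,
                          mt_read_counts = rowSums(ds$mt_counts),
                          iterations = 25, seed = 1)
  rep <- res$report
  get <- function(s, col) rep[[col]][rep$sample == s]

  expect_equal(get("H01", "final_status"), "healthy")
  expect_equal(get("H01", "rationale"), "retained")
  # putative rotten but clusters with (and looks like) healthy
  expect_equal(get("H04", "final_status"), "healthy")
  expect_equal(get("H04", "rationale"), "reassigned_by_cluster")
  # transitional MG + active focal MT -> rescued
  expect_equal(get("R03", "final_status"), "healthy")
  expect_equal(get("R03", "rationale"), "rescued_by_MT")
  # transitional MG + silent focal MT -> rotten
  expect_equal(get("R04", "final_status"), "rotten")
  expect_true(get("R04", "rationale") %in% c("retained"))
  expect_equal(get("R01", "final_status"), "rotten")
  expect_true(all(rep$cluster_support >= 0 & rep$cluster_support <= 1))
  expect_lte(sum(res$pca$explained_variance), 1 + 1e-12)
})

test_that("classify_samples excludes low-read MT layers", {
  ds <- small_dataset(seed = 23, n_healthy = 3, n_rotten = 3, depth = 3e4)
  ds <- make_transitional(ds, "R02", 0.05, 0.60, seed = 2)
  lens <- gene_lengths(ds$annotations)
  mg <- compute_tpm(ds$mg_counts, lens)
  mt <- compute_tpm(ds$mt_counts, lens)
  putative <- stats::setNames(
    ifelse(startsWith(rownames(mg), "H"), "healthy", "rotten"), rownames(mg)
  )
  reads <- stats::setNames(rep(1e5, 6), rownames(mg))
  reads["R02"] <- 3000  # below the 3500 floor
  res <- classify_samples(mg, mt, lineage_cols(ds$annotations),
                          "Polyporaceae:Fomes", putative,
                          mt_read_counts = reads, iterations = 10, seed = 1)
  row <- res$report[sample == "R02"]
  expect_true(row$mt_excluded)
  # without a usable MT layer the intermediate sample cannot be rescued
  expect_equal(row$final_status, "rotten")
  expect_equal(row$rationale, "excluded_low_reads")
})

test_that("focal_share errors when the focal taxon is absent", {
  lin <- make_lineages("g1", "Bacteria;P;C;O;FamA")
  tpm <- tiny_tpm(matrix(1e6), genes = "g1")
  expect_error(focal_share(tpm, lin, "Polyporaceae:Fomes"), "absent")
})
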