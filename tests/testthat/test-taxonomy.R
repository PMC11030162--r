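test_that("assign_best_hit picks max bitscore with deterministic tie-breaks", {
  taxmap <- cbind(
    data.table::data.table(subject_id = c("a1", "b1", "s1", "s2")),
    split_lineage(c("Bacteria;P;C;O;FamTie", "Bacteria;P;C;O;FamB",
                    "Bacteria;P;C;O;FamA", "Bacteria;P;C;O;FamB"))
  )
  mk_hit <- function(q, s, bits, ev = 1e-10) data.table::data.table(
    query_id = q, subject_id = s, percent_identity = 90, align_length = 100L,
    mismatches = 0L, gap_opens = 0L, qstart = 1L, qend = 100L,
    sstart = 1L, send = 100L, evalue = ev, bitscore = bits
  )
  hits <- rbind(
    mk_hit("g1", "s1", 50.1), mk_hit("g1", "s2", 200.3),
    mk_hit("g2", "a1", 100), mk_hit("g2", "b1", 100)
  )
  lin <- assign_best_hit(hits, taxmap, genes = c("g1", "g2", "g3"))
  expect_equal(lin[gene_id == "g1"]$family, "FamB")   # strict maximum
  expect_equal(lin[gene_id == "g2"]$family, "FamTie") # 'a1' < 'b1'
  expect_true(is.na(lin[gene_id == "g3"]$family))     # no hits -> unassigned

  # evalue breaks a bitscore tie before subject id
  hits2 <- rbind(mk_hit("g4", "b1", 100, ev = 1e-30),
                 mk_hit("g4", "a1", 100, ev = 1e-10))
  expect_equal(assign_best_hit(hits2, taxmap)$family, "FamB")

  # uncovered subject warns and yields unassigned
  expect_warning(
    lin3 <- assign_best_hit(mk_hit("g5", "zz", 80), taxmap),
    "missing from taxmap"
  )
  expect_true(is.na(lin3$family))
})

test_that("assign_best_hit equals the exhaustive-scan oracle", {
  set.seed(101)
  for (i in 1:200) {
    rt <- random_hit_table()
    got <- assign_best_hit(rt$hits, rt$taxmap)
    want <- best_hit_oracle(rt$hits, rt$taxmap)
    data.table::setorder(got, gene_id)
    data.table::setorder(want, gene_id)
    expect_equal(got$family, want$family)
    expect_equal(got$phylum, want$phylum)
  }
})

test_that("aggregate_by_rank sums mass, rolls up truncated lineages", {
  lin <- make_lineages(
    c("g1", "g2", "g3", "g4"),
    c("Eukaryota;Asco;S;O1;FamA", "Eukaryota;Asco;S;O1;FamA",
      "Eukaryota;Asco;S;OrdX", "")
  )
  tpm <- tiny_tpm(matrix(c(3e5, 2e5, 4e5, 1e5), nrow = 1),
                  samples = "S1", genes = c("g1", "g2", "g3", "g4"))
  prof <- aggregate_by_rank(tpm, lin, "family")
  expect_equal(prof[taxon == "FamA"]$tpm, 5e5)          # hand sum
  expect_equal(prof[taxon == "unclassified OrdX"]$tpm, 4e5)
  expect_equal(prof[taxon == "unassigned"]$tpm, 1e5)
  expect_equal(sum(prof$tpm), 1e6)                       # mass conserved
  expect_error(aggregate_by_rank(tpm, lin, "genus"), "floor")

  # all genes unassigned
  lin0 <- make_lineages("g1", "")
  p0 <- aggregate_by_rank(tiny_tpm(matrix(1e6), genes = "g1"), lin0, "family")
  expect_equal(p0$taxon, "unassigned")
  expect_equal(p0$tpm, 1e6)

  # permutation invariance in gene order
  perm <- sample(colnames(tpm))
  prof2 <- aggregate_by_rank(tpm[, perm, drop = FALSE], lin, "family")
  expect_equal(prof[order(taxon)]$tpm, prof2[order(taxon)]$tpm)
})

test_that("group_below_threshold merges by share of total mass", {
  prof <- data.table::data.table(
    sample = "S1", taxon = c("A", "B", "C"),
    tpm = c(0.6, 0.395, 0.005) * 1e6
  )
  g <- group_below_threshold(prof)
  expect_setequal(g$taxon, c("A", "B", "Below 1%"))
  expect_equal(g[taxon == "Below 1%"]$tpm, 5000)
  expect_equal(sum(g$tpm), 1e6)

  # all above threshold: unchanged
  hi <- data.table::data.table(sample = "S1", taxon = c("A", "B"),
                               tpm = c(6e5, 4e5))
  expect_equal(group_below_threshold(hi)[order(taxon)]$tpm, c(6e5, 4e5))

  # many small taxa all merge even though their sum is large
  small <- data.table::data.table(
    sample = "S1", taxon = sprintf("T%03d", 1:200), tpm = rep(5e3, 200)
  )
  gs <- group_below_threshold(small)
  expect_equal(gs$taxon, "Below 1%")
  expect_equal(gs$tpm, 1e6)

  # oracle: filter-and-sum
  set.seed(9)
  tax <- sprintf("T%02d", 1:30)
  p <- data.table::data.table(
    sample = rep(c("S1", "S2"), each = 30), taxon = rep(tax, 2),
    tpm = stats::runif(60, 0, 1e5)
  )
  g2 <- group_below_threshold(p, 0.02)
  tot <- sum(p$tpm)
  low <- tax[vapply(tax, function(t) sum(p[taxon == t]$tpm), 0) / tot < 0.02]
  expect_equal(sum(g2[taxon == "Below 1%"]$tpm),
               sum(p[taxon %in% low]$tpm))
  expect_equal(sum(g2$tpm), tot)
  # 'unassigned' pseudo-category is never merged
  pu <- data.table::data.table(sample = "S1",
                               taxon = c("A", "unassigned"),
                               tpm = c(999000, 1000))
  expect_true("unassigned" %in% group_below_threshold(pu)$taxon)
})

test_that("family_richness counts distinct real families with TPM > 0", {
  lin <- make_lineages(
    c("g1", "g2", "g3", "g4"),
    c("Bacteria;P;C;O;FamA", "Bacteria;P;C;O;FamA",
      "Bacteria;P;C;O;FamB", "")
  )
  tpm <- tiny_tpm(rbind(c(1, 1, 1, 5), c(0, 1, 0, 5)),
                  samples = c("S1", "S2"),
                  genes = c("g1", "g2", "g3", "g4"))
  r <- family_richness(tpm, lin,
                       groups = c(S1 = "rotten", S2 = "healthy"))
  expect_equal(unname(r$per_sample), c(2L, 1L))  # unassigned excluded
  expect_equal(unname(r$group_medians[c("rotten", "healthy")]), c(2, 1))

  # planted-community recovery: every family with nonzero mass is counted
  ds <- small_dataset(seed = 8, depth = 5e4)
  lin_s <- lineage_cols(ds$annotations)
  tpm_s <- compute_tpm(ds$mg_counts, gene_lengths(ds$annotations))
  rs <- family_richness(tpm_s, lin_s)
  fam_of <- stats::setNames(lin_s$family, lin_s$gene_id)
  for (s in rownames(tpm_s)) {
    expected <- length(unique(stats::na.omit(
      fam_of[colnames(tpm_s)[tpm_s[s, ] > 0]]
    )))
    expect_equal(unname(rs$per_sample[s]), expected)
  }
})

test_that("aggregation conserves mass on generated data", {
  ds <- small_dataset(seed = 12, depth = 2e4)
  tpm <- compute_tpm(ds$mg_counts, gene_lengths(ds$annotations))
  lin <- lineage_cols(ds$annotations)
  for (rank in c("superkingdom", "phylum", "family")) {
    prof <- aggregate_by_rank(tpm, lin, rank)
    per_sample <- prof[, .(tot = sum(tpm)), by = sample]
    expect_equal(per_sample$tot, rep(1e6, nrow(tpm)), tolerance = 1e-6)
    g <- group_below_threshold(prof)
    expect_equal(sum(g$tpm), sum(prof$tpm), tolerance = 1e-9)
  }
})
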