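test_that("parse_definition implements the grammar with '+' > ',' > space", {
  e <- parse_definition("K00001 K00002")
  expect_equal(e$type, "and")
  expect_equal(vapply(e$children, `[[`, character(1), "ko"),
               c("K00001", "K00002"))

  e <- parse_definition("K02588+K02586+K02591")
  expect_equal(e$type, "complex")
  expect_equal(length(e$children), 3L)

  e <- parse_definition("(K00001,K00002) K00003 -K00004")
  expect_equal(e$type, "and")
  expect_equal(vapply(e$children, `[[`, character(1), "type"),
               c("or", "leaf", "optional"))
  expect_equal(deparse_definition(e), "K00001,K00002 K00003 -K00004")

  # ',' binds tighter than space: no parens needed around the OR
  expect_identical(parse_definition("K00001,K00002 K00003"),
                   parse_definition("(K00001,K00002) K00003"))
  # '+' binds tighter than ','
  e <- parse_definition("K00001+K00002,K00003")
  expect_equal(e$type, "or")
  expect_equal(e$children[[1]]$type, "complex")

  # optional complex subunit vs optional step
  e1 <- parse_definition("K00001-K00002")
  expect_equal(e1$type, "complex")
  expect_equal(e1$children[[2]]$type, "optional")
  e2 <- parse_definition("K00001 -K00002")
  expect_equal(e2$type, "and")
  expect_equal(e2$children[[2]]$type, "optional")

  expect_equal(parse_definition("--")$type, "wildcard")
})

test_that("parse_definition reports malformed input with position", {
  expect_error(parse_definition("K00001 (K00002"), "unbalanced")
  expect_error(parse_definition("K00001 & K00002"), "position 8")
  expect_error(parse_definition("K1 K00002"), "position")
  expect_error(parse_definition("K00001,"), "unexpected end")
})

test_that("parse -> deparse -> parse is a fixed point", {
  # packaged module file
  mods <- read_module_flatfile(
    system.file("extdata", "modules_synthetic.txt", package = "fbmeta")
  )
  for (d in mods$definition) {
    tree <- parse_definition(d)
    expect_identical(parse_definition(deparse_definition(tree)), tree,
                     label = d)
  }
  # random trees built independently of the parser
  set.seed(42)
  kos <- sprintf("K%05d", 1:8)
  for (i in 1:300) {
    tree <- random_module_expr(kos, depth = 3L)
    s <- deparse_definition(tree)
    expect_identical(parse_definition(s), tree, label = s)
  }
})

test_that("evaluate_module matches the worked completeness semantics", {
  r <- evaluate_module("K00001 K00002", c("K00001", "K00002"))
  expect_true(r$complete)
  expect_equal(r$satisfied_fraction, 1)
  expect_equal(r$missing_kos, character(0))

  r <- evaluate_module("K02588+K02586+K02591", character(0))
  expect_false(r$complete)
  expect_equal(r$satisfied_fraction, 0)
  expect_equal(r$missing_kos, c("K02586", "K02588", "K02591"))

  # OR branch satisfied by either alternative
  expect_true(evaluate_module("(K00001,K00002) K00003",
                              c("K00002", "K00003"))$complete)

  # optional steps never counted in the denominator
  r <- evaluate_module("K00001 -K00002", "K00001")
  expect_true(r$complete)
  expect_equal(r$satisfied_fraction, 1)

  # partial fraction over top-level steps
  r <- evaluate_module("K00001 K00002 K00003", c("K00001", "K00003"))
  expect_false(r$complete)
  expect_equal(r$satisfied_fraction, 2 / 3)
  expect_equal(r$missing_kos, "K00002")

  # wildcard semantics are switchable
  expect_true(evaluate_module("K00001 --", "K00001")$complete)
  r <- evaluate_module("K00001 --", "K00001", wildcard_satisfied = FALSE)
  expect_false(r$complete)
  expect_true(is.na(r$missing_kos[1]))
})

test_that("missing_kos picks the cheapest OR branch with lexicographic ties", {
  # cheaper branch wins
  r <- evaluate_module("(K00001+K00002,K00003)", character(0))
  expect_equal(r$missing_kos, "K00003")
  # equal cardinality: lexicographically smaller set
  r <- evaluate_module("(K00005,K00002)", character(0))
  expect_equal(r$missing_kos, "K00002")
  # partially satisfied complex is cheaper to finish
  r <- evaluate_module("(K00001+K00002,K00003+K00004)", "K00001")
  expect_equal(r$missing_kos, "K00002")
})

test_that("evaluate agrees with the truth-table oracle on random expressions", {
  set.seed(7)
  kos <- sprintf("K%05d", 1:6)
  for (i in 1:200) {
    tree <- random_module_expr(kos, depth = 3L)
    used <- expr_kos(tree)
    subsets <- if (length(used) == 0) list(character(0)) else {
      lapply(0:(2^length(used) - 1), function(mask) {
        used[bitwAnd(mask, 2^(seq_along(used) - 1)) > 0]
      })
    }
    for (present in subsets) {
      expect_identical(
        fbmeta:::eval_expr(tree, present),
        oracle_verdict(tree, present),
        label = deparse_definition(tree)
      )
    }
  }
})

test_that("completeness is monotone in the present-KO set", {
  set.seed(13)
  kos <- sprintf("K%05d", 1:8)
  for (i in 1:50) {
    tree <- random_module_expr(kos, depth = 3L)
    present <- sample(kos, 3)
    base <- evaluate_module(tree, present)
    grown <- evaluate_module(tree, union(present, sample(kos, 3)))
    expect_gte(grown$satisfied_fraction, base$satisfied_fraction)
    if (base$complete) expect_true(grown$complete)
  }
})

test_that("screen_modules pools the community and screens abundant families", {
  # module split across two families: complete for the community,
  # incomplete for each family
  modules <- data.table::data.table(
    module_id = "M99999", name = "split",
    definition = "K00010 K00011"
  )
  ann <- data.table::data.table(
    gene_id = c("a1", "b1", "c1"),
    lineage = c("Bacteria;P1;C1;O1;FamA", "Bacteria;P1;C1;O1;FamB",
                "Bacteria;P1;C1;O1;FamC")
  )
  lin <- make_lineages(ann$gene_id, ann$lineage)
  annotations <- c(a1 = "K00010", b1 = "K00011", c1 = "K00012")
  # FamC at 0.5% of bacterial TPM stays below the screen threshold
  tpm <- tiny_tpm(
    rbind(c(497500, 497500, 5000), c(497500, 497500, 5000)),
    samples = c("S1", "S2"), genes = c("a1", "b1", "c1")
  )
  res <- screen_modules(modules, tpm, annotations, lin)
  comm <- res[scope == "community"]
  expect_true(all(comm$complete))
  fams <- res[scope != "community"]
  expect_setequal(fams$scope, c("FamA", "FamB"))  # FamC below 1%
  expect_false(any(fams$complete))
  expect_equal(fams[scope == "FamA"]$missing_kos, "K00011")
})

test_that("nitrogenase_screen reports per-sample per-layer subunit presence", {
  annotations <- c(g1 = "K02586", g2 = "K00001")
  mg <- tiny_tpm(rbind(c(10, 90), c(0, 100)), c("S1", "S2"), c("g1", "g2"))
  mt <- tiny_tpm(rbind(c(0, 100), c(0, 100)), c("S1", "S2"), c("g1", "g2"))
  res <- nitrogenase_screen(annotations,
                            list(metagenome = mg, metatranscriptome = mt))
  expect_equal(nrow(res), 2 * 2 * 3)
  nifd_mg_s1 <- res[sample == "S1" & layer == "metagenome" & subunit == "nifD"]
  expect_true(nifd_mg_s1$present)
  expect_false(any(res[!(sample == "S1" & layer == "metagenome" &
                           subunit == "nifD")]$present))
})
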