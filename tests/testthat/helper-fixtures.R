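# Shared fixtures and independent oracles. Everything here is deliberately
# written on a different code path than the implementation it checks.

RANKS <- c("superkingdom", "phylum", "class", "order", "family", "genus")

# tiny lineage table from semicolon strings
make_lineages <- function(ids, lineage_strings) {
  cbind(
    data.table::data.table(gene_id = ids),
    fbmeta::split_lineage(lineage_strings)
  )
}

tiny_tpm <- function(m, samples = NULL, genes = NULL) {
  m <- as.matrix(m)
  rownames(m) <- samples %||% sprintf("S%d", seq_len(nrow(m)))
  colnames(m) <- genes %||% sprintf("g%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- random module expressions (built directly, not via the parser) --------

expr_node_ <- function(type, children = list(), ko = NA_character_) {
  structure(list(type = type, children = children, ko = ko),
            class = "module_expr")
}

random_module_expr <- function(kos, depth = 3L, inside_optional = FALSE) {
  if (depth <= 0L || stats::runif(1) < 0.35) {
    # a wildcard directly under optional would serialize to '---'
    if (!inside_optional && stats::runif(1) < 0.05) {
      return(expr_node_("wildcard"))
    }
    return(expr_node_("leaf", ko = sample(kos, 1L)))
  }
  type <- sample(c("and", "or", "complex", "optional"), 1L,
                 prob = c(0.3, 0.3, 0.25, 0.15))
  if (type == "optional") {
    if (inside_optional) return(expr_node_("leaf", ko = sample(kos, 1L)))
    # an optional child that is itself optional would serialize to '--'
    return(expr_node_(
      "optional",
      list(random_module_expr(kos, depth - 1L, inside_optional = TRUE))
    ))
  }
  n <- sample(2:3, 1L)
  children <- lapply(seq_len(n), function(i) {
    ch <- random_module_expr(kos, depth - 1L, inside_optional)
    # leading-position optionals in and/or would change meaning on reparse
    # only inside complex chains, which the serializer handles; but an
    # optional directly under optional is excluded above.
    ch
  })
  if (type == "complex") {
    # complex members that are optional are legal ('-' joined)
    return(expr_node_("complex", children))
  }
  # 'and'/'or' children that are optional are legal standalone steps
  expr_node_(type, children)
}

# independent truth-table evaluation: compile to an R logical expression
expr_to_logic <- function(node) {
  switch(node$type,
    leaf = sprintf('("%s" %%in%% present)', node$ko),
    wildcard = "wc",
    optional = "TRUE",
    and = ,
    complex = paste0(
      "(", paste(vapply(node$children, expr_to_logic, character(1)),
                 collapse = " && "), ")"
    ),
    or = paste0(
      "(", paste(vapply(node$children, expr_to_logic, character(1)),
                 collapse = " || "), ")"
    )
  )
}

oracle_verdict <- function(node, present, wc = TRUE) {
  eval(parse(text = expr_to_logic(node)),
       list(present = present, wc = wc))
}

expr_kos <- function(node) {
  if (node$type == "leaf") return(node$ko)
  sort(unique(unlist(lapply(node$children, expr_kos))))
}

# ---- exhaustive best-hit oracle --------------------------------------------

best_hit_oracle <- function(hits, taxmap) {
  hits <- as.data.frame(hits)
  taxmap <- as.data.frame(taxmap)
  out <- list()
  for (q in sort(unique(hits$query_id))) {
    h <- hits[hits$query_id == q, ]
    best <- h[1, ]
    if (nrow(h) > 1) {
      for (i in 2:nrow(h)) {
        r <- h[i, ]
        better <- r$bitscore > best$bitscore ||
          (r$bitscore == best$bitscore && r$evalue < best$evalue) ||
          (r$bitscore == best$bitscore && r$evalue == best$evalue &&
             r$subject_id < best$subject_id)
        if (better) best <- r
      }
    }
    row <- taxmap[taxmap$subject_id == best$subject_id, ]
    lin <- if (nrow(row) == 1) {
      unlist(row[RANKS])
    } else {
      stats::setNames(rep(NA_character_, 6), RANKS)
    }
    out[[q]] <- lin
  }
  res <- data.table::data.table(gene_id = names(out))
  for (r in RANKS) {
    data.table::set(res, j = r,
                    value = vapply(out, `[[`, character(1), r))
  }
  res
}

random_hit_table <- function(n_genes = 10L, n_subjects = 6L) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  subjects <- sprintf("s%02d", seq_len(n_subjects))
  rows <- lapply(genes, function(g) {
    k <- sample(1:4, 1L)
    data.table::data.table(
      query_id = g,
      subject_id = sample(subjects, k, replace = TRUE),
      percent_identity = 90, align_length = 100L, mismatches = 1L,
      gap_opens = 0L, qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
      # coarse grids engineer frequent bitscore and evalue ties
      evalue = sample(c(1e-10, 1e-20, 1e-30), k, replace = TRUE),
      bitscore = sample(seq(50, 150, by = 25), k, replace = TRUE)
    )
  })
  hits <- data.table::rbindlist(rows)
  taxmap <- data.table::data.table(
    subject_id = subjects,
    lineage = sprintf("Bacteria;Phylum%d;ClassX;OrderY;Fam%02d",
                      seq_len(n_subjects) %% 3L + 1L, seq_len(n_subjects))
  )
  list(hits = hits, taxmap = cbind(
    taxmap[, .(subject_id)], fbmeta::split_lineage(taxmap$lineage)
  ))
}

# small fast community for unit tests (not the acceptance world)
small_dataset <- function(seed = 1L, n_healthy = 3L, n_rotten = 3L,
                          depth = 2e4) {
  fbmeta::generate_community(
    fbmeta::community_spec(depth = depth),
    n_healthy = n_healthy, n_rotten = n_rotten, seed = seed
  )
}

lineage_cols <- function(ann) {
  ann[, c("gene_id", RANKS), with = FALSE]
}

gene_lengths <- function(ann) {
  stats::setNames(ann$length_bp, ann$gene_id)
}

ko_map_of <- function(ann) {
  stats::setNames(ann$ko, ann$gene_id)[nzchar(ann$ko)]
}

dbcan_of <- function(ann) {
  ann[nzchar(cazy_families),
      .(cazy_family = strsplit(cazy_families, ",")[[1L]]),
      by = "gene_id"]
}
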