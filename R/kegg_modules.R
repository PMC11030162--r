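# KEGG module DEFINITION logic.
#
# A DEFINITION string encodes the KO requirements of a pathway module:
#   space  separates AND-ed reaction steps (weakest binder)
#   ','    separates OR alternatives
#   '+'    joins obligatory complex subunits (tightest binder)
#   '-'    prefixes an optional component (never blocks completeness)
#   '--'   a wildcard step with no KO assigned
#   '()'   group
# Precedence: '+' > ',' > space. The parser below is a recursive-descent
# implementation of that grammar; trees round-trip through
# deparse_definition() as a fixed point.

KO_PATTERN <- "^K\\d{5}$"

expr_node <- function(type, children = list(), ko = NA_character_) {
  structure(list(type = type, children = children, ko = ko),
            class = "module_expr")
}

tokenize_definition <- function(definition) {
  # space is semantically significant (AND separator): 'K1 -K2' is an
  # optional *step*, 'K1-K2' an optional complex subunit. Runs of whitespace
  # collapse to a single space token. '--' must be matched before '-'.
  pat <- "K\\d{5}|--|\\s+|[(),+-]"
  starts <- gregexpr(pat, definition)[[1L]]
  if (starts[1L] == -1L) {
    stop("parse_definition: empty or unrecognizable definition", call. = FALSE)
  }
  toks <- regmatches(definition, gregexpr(pat, definition))[[1L]]
  covered <- sum(nchar(toks))
  if (covered != nchar(definition)) {
    # locate first position not covered by any token
    pos <- rep(FALSE, nchar(definition))
    ends <- starts + nchar(toks) - 1L
    for (i in seq_along(starts)) pos[starts[i]:ends[i]] <- TRUE
    bad <- which(!pos)[1L]
    stop(sprintf(
      "parse_definition: illegal token at position %d ('%s')",
      bad, substr(definition, bad, bad)
    ), call. = FALSE)
  }
  toks[grepl("^\\s+$", toks)] <- " "
  # drop leading/trailing space tokens
  keep <- rep(TRUE, length(toks))
  if (toks[1L] == " ") keep[1L] <- FALSE
  if (toks[length(toks)] == " ") keep[length(toks)] <- FALSE
  list(tokens = toks[keep], pos = starts[keep])
}

#' Parse a KEGG module DEFINITION string into an expression tree
#'
#' @param definition The raw DEFINITION string.
#' @return A `module_expr` tree with node types `and`, `or`, `complex`,
#'   `optional`, `wildcard` and `leaf`.
#' @seealso [deparse_definition()], [evaluate_module()]
#' @export
parse_definition <- function(definition) {
  stopifnot(is.character(definition), length(definition) == 1L)
  if (!balanced_parens(definition)) {
    stop("parse_definition: unbalanced parentheses", call. = FALSE)
  }
  tk <- tokenize_definition(definition)
  st <- new.env(parent = emptyenv())
  st$tokens <- tk$tokens
  st$pos <- tk$pos
  st$i <- 1L
  expr <- parse_and(st)
  if (st$i <= length(st$tokens)) {
    stop(sprintf(
      "parse_definition: unexpected token '%s' at position %d",
      st$tokens[st$i], st$pos[st$i]
    ), call. = FALSE)
  }
  expr
}

peek <- function(st) {
  if (st$i > length(st$tokens)) NA_character_ else st$tokens[st$i]
}
advance <- function(st) {
  t <- st$tokens[st$i]
  st$i <- st$i + 1L
  t
}

# expr := chain (SPACE chain)*  (space = AND; weakest binder)
parse_and <- function(st) {
  steps <- list(parse_or(st))
  while (identical(peek(st), " ")) {
    advance(st)
    if (is.na(peek(st)) || identical(peek(st), ")")) break
    steps <- c(steps, list(parse_or(st)))
  }
  if (length(steps) == 1L) steps[[1L]] else expr_node("and", steps)
}

# chain := alt (',' alt)*
parse_or <- function(st) {
  alts <- list(parse_complex(st))
  while (identical(peek(st), ",")) {
    advance(st)
    alts <- c(alts, list(parse_complex(st)))
  }
  if (length(alts) == 1L) alts[[1L]] else expr_node("or", alts)
}

# alt := ['-'] unit (('+'|'-') unit)*   -- '-' members are optional subunits
parse_complex <- function(st) {
  members <- list()
  if (identical(peek(st), "-")) {
    advance(st)
    members <- list(expr_node("optional", list(parse_unit(st))))
  } else {
    members <- list(parse_unit(st))
  }
  while (!is.na(peek(st)) && peek(st) %in% c("+", "-")) {
    op <- advance(st)
    u <- parse_unit(st)
    if (op == "-") u <- expr_node("optional", list(u))
    members <- c(members, list(u))
  }
  if (length(members) == 1L) members[[1L]] else expr_node("complex", members)
}

parse_unit <- function(st) {
  t <- peek(st)
  if (is.na(t)) {
    stop("parse_definition: unexpected end of definition", call. = FALSE)
  }
  if (t == "(") {
    advance(st)
    e <- parse_and(st)
    if (!identical(peek(st), ")")) {
      stop(sprintf(
        "parse_definition: expected ')' at position %d",
        if (st$i <= length(st$pos)) st$pos[st$i] else nchar("")
      ), call. = FALSE)
    }
    advance(st)
    return(e)
  }
  if (t == "--") {
    advance(st)
    return(expr_node("wildcard"))
  }
  if (grepl(KO_PATTERN, t)) {
    advance(st)
    return(expr_node("leaf", ko = t))
  }
  stop(sprintf(
    "parse_definition: unexpected token '%s' at position %d", t, st$pos[st$i]
  ), call. = FALSE)
}

#' Serialize a module expression tree back to a DEFINITION string
#'
#' Produces a canonical form: `parse_definition(deparse_definition(x))`
#' reproduces `x` exactly.
#'
#' @param expr A `module_expr` tree.
#' @return A single DEFINITION string.
#' @export
deparse_definition <- function(expr) {
  wrap <- function(s, need) if (need) paste0("(", s, ")") else s
  rec <- function(node, ctx) {
    switch(node$type,
      leaf = node$ko,
      wildcard = "--",
      optional = {
        # leading '-' inside a complex is emitted by the complex branch;
        # a standalone optional step serializes as -X
        inner <- rec(node$children[[1L]], "complex")
        paste0("-", inner)
      },
      complex = {
        parts <- vapply(node$children, function(ch) {
          if (ch$type == "optional") {
            paste0("-", rec(ch$children[[1L]], "complex"))
          } else {
            paste0("+", rec(ch, "complex"))
          }
        }, character(1))
        parts[1L] <- sub("^\\+", "", parts[1L])
        wrap(paste(parts, collapse = ""), ctx == "complex")
      },
      or = {
        s <- paste(
          vapply(node$children, rec, character(1), ctx = "or"),
          collapse = ","
        )
        # same-type nesting keeps explicit parens so reparsing does not
        # flatten the tree
        wrap(s, ctx %in% c("complex", "or"))
      },
      and = {
        s <- paste(
          vapply(node$children, rec, character(1), ctx = "and"),
          collapse = " "
        )
        wrap(s, ctx %in% c("or", "complex", "and"))
      },
      stop("unknown node type: ", node$type)
    )
  }
  out <- rec(expr, "top")
  # a complex first member that is itself or/and was wrapped; also wrap an
  # or/and first member context handled above -- nothing else to do
  out
}

#' @export
print.module_expr <- function(x, ...) {
  cat("<module_expr> ", deparse_definition(x), "\n", sep = "")
  invisible(x)
}

#' Collect the KO ids appearing in a module expression
#'
#' @param expr A `module_expr` tree.
#' @param include_optional Include KOs under optional components (default TRUE).
#' @return Sorted unique character vector of KO ids.
#' @export
module_kos <- function(expr, include_optional = TRUE) {
  rec <- function(node) {
    if (node$type == "leaf") return(node$ko)
    if (node$type == "optional" && !include_optional) return(character(0))
    unlist(lapply(node$children, rec))
  }
  sort(unique(rec(expr)))
}

# Verdict-only evaluation; kept lean because the truth-table acceptance
# criterion calls it hundreds of thousands of times.
eval_expr <- function(node, present, wildcard_satisfied = TRUE) {
  switch(node$type,
    leaf = node$ko %in% present,
    wildcard = wildcard_satisfied,
    optional = TRUE,
    and = ,
    complex = {
      for (ch in node$children) {
        if (!eval_expr(ch, present, wildcard_satisfied)) return(FALSE)
      }
      TRUE
    },
    or = {
      for (ch in node$children) {
        if (eval_expr(ch, present, wildcard_satisfied)) return(TRUE)
      }
      FALSE
    },
    stop("unknown node type: ", node$type)
  )
}

# Minimal-cardinality KO set completing a node; NULL = infeasible
# (an unsatisfied wildcard cannot be completed by adding KOs).
missing_set <- function(node, present, wildcard_satisfied = TRUE) {
  switch(node$type,
    leaf = if (node$ko %in% present) character(0) else node$ko,
    wildcard = if (wildcard_satisfied) character(0) else NULL,
    optional = character(0),
    and = ,
    complex = {
      acc <- character(0)
      for (ch in node$children) {
        m <- missing_set(ch, present, wildcard_satisfied)
        if (is.null(m)) return(NULL)
        acc <- union(acc, m)
      }
      sort(acc)
    },
    or = {
      best <- NULL
      best_key <- NULL
      for (ch in node$children) {
        m <- missing_set(ch, present, wildcard_satisfied)
        if (is.null(m)) next
        key <- paste(sort(m), collapse = ",")
        if (is.null(best) || length(m) < length(best) ||
            (length(m) == length(best) && key < best_key)) {
          best <- sort(m)
          best_key <- key
        }
      }
      best
    },
    stop("unknown node type: ", node$type)
  )
}

#' Evaluate module completeness against a set of present KOs
#'
#' The top-level AND steps of the definition are scored individually;
#' `satisfied_fraction` is the fraction of non-optional top-level steps whose
#' subtree evaluates true, and `missing_kos` is the minimal-cardinality KO set
#' (cheapest OR branch, ties broken lexicographically) that would complete the
#' module.
#'
#' @param expr A `module_expr` tree (or a DEFINITION string, parsed on the fly).
#' @param present Character vector of present KO ids.
#' @param wildcard_satisfied Treat `--` wildcard steps as satisfied
#'   (default TRUE, the KEGG reading that a step with no KO assigned cannot be
#'   tested); set FALSE to count them unsatisfiable.
#' @return A list with `complete` (logical), `satisfied_fraction` (in `[0,1]`),
#'   `missing_kos` (character; `NA` when no KO addition can complete the
#'   module, i.e. an unsatisfied wildcard blocks it).
#' @export
evaluate_module <- function(expr, present, wildcard_satisfied = TRUE) {
  if (is.character(expr)) expr <- parse_definition(expr)
  steps <- if (expr$type == "and") expr$children else list(expr)
  scored <- steps[vapply(steps, function(s) s$type != "optional", logical(1))]
  if (length(scored) == 0L) {
    frac <- 1
  } else {
    frac <- mean(vapply(
      scored, eval_expr, logical(1),
      present = present, wildcard_satisfied = wildcard_satisfied
    ))
  }
  complete <- frac == 1
  miss <- missing_set(expr, present, wildcard_satisfied)
  list(
    complete = complete,
    satisfied_fraction = frac,
    missing_kos = if (is.null(miss)) NA_character_ else miss
  )
}

#' Screen modules for completeness in the bacterial community
#'
#' Evaluates each module against the KOs carried by *bacterial* genes with
#' TPM > 0, pooled per sample group (typically the healthy/rotten condition
#' groups), both community-wide and per highly-abundant bacterial family
#' (those contributing more than `family_threshold` of the bacterial TPM in
#' the group).
#'
#' @param modules A data.frame with columns `module_id`, `definition`
#'   (as from [read_module_flatfile()]).
#' @param tpm A TPM matrix (samples x genes), see [compute_tpm()].
#' @param annotations Named character vector `gene_id -> KO`.
#' @param lineages A data.frame with `gene_id` and rank columns
#'   (see [split_lineage()]).
#' @param groups Named character vector `sample -> group label`; defaults to
#'   one pooled group `"community"` over all samples.
#' @param per_family Also evaluate per abundant bacterial family
#'   (default TRUE).
#' @param family_threshold Bacterial-TPM share above which a family is
#'   screened (default 0.01).
#' @param wildcard_satisfied Passed to [evaluate_module()].
#' @return A `data.table` with one row per (module, group, scope):
#'   `module_id`, `group`, `scope` ("community" or a family name),
#'   `complete`, `satisfied_fraction`, `missing_kos` (comma-joined).
#' @export
screen_modules <- function(modules, tpm, annotations, lineages,
                           groups = NULL, per_family = TRUE,
                           family_threshold = 0.01,
                           wildcard_satisfied = TRUE) {
  modules <- data.table::as.data.table(modules)
  lin <- data.table::as.data.table(lineages)
  if (is.null(groups)) {
    groups <- stats::setNames(rep("community", nrow(tpm)), rownames(tpm))
  }
  if (!all(rownames(tpm) %in% names(groups))) {
    stop("screen_modules: every sample needs a group label", call. = FALSE)
  }
  bact_genes <- lin$gene_id[!is.na(lin$superkingdom) &
                              lin$superkingdom == "Bacteria"]
  bact_genes <- intersect(bact_genes, colnames(tpm))
  gene_fam <- stats::setNames(lin$family, lin$gene_id)
  exprs <- lapply(modules$definition, parse_definition)

  res <- list()
  for (g in unique(groups[rownames(tpm)])) {
    smp <- rownames(tpm)[groups[rownames(tpm)] == g]
    sub <- tpm[smp, bact_genes, drop = FALSE]
    present_comm <- present_kos(
      tpm[smp, , drop = FALSE], annotations, scope = bact_genes, pooled = TRUE
    )
    scopes <- list(community = bact_genes)
    if (per_family && length(bact_genes) > 0L) {
      fam_tpm <- tapply(colSums(sub), gene_fam[bact_genes], sum)
      fam_tpm <- fam_tpm[!is.na(names(fam_tpm))]
      tot <- sum(sub)
      if (tot > 0) {
        abundant <- names(fam_tpm)[fam_tpm / tot > family_threshold]
        for (f in sort(abundant)) {
          scopes[[f]] <- bact_genes[!is.na(gene_fam[bact_genes]) &
                                      gene_fam[bact_genes] == f]
        }
      }
    }
    for (sc in names(scopes)) {
      present <- if (sc == "community") present_comm else {
        present_kos(tpm[smp, , drop = FALSE], annotations,
                    scope = scopes[[sc]], pooled = TRUE)
      }
      for (k in seq_len(nrow(modules))) {
        ev <- evaluate_module(exprs[[k]], present, wildcard_satisfied)
        res[[length(res) + 1L]] <- data.table::data.table(
          module_id = modules$module_id[k],
          group = g,
          scope = sc,
          complete = ev$complete,
          satisfied_fraction = ev$satisfied_fraction,
          missing_kos = paste(ev$missing_kos, collapse = ",")
        )
      }
    }
  }
  data.table::rbindlist(res)
}

NITROGENASE_KOS <- c(nifH = "K02588", nifD = "K02586", nifK = "K02591")

#' Screen samples for nitrogenase subunit genes
#'
#' Reports, per sample and omic layer, whether any gene annotated with each
#' nitrogenase subunit KO (nifH = K02588, nifD = K02586, nifK = K02591) has
#' TPM > 0.
#'
#' @param annotations Named character vector `gene_id -> KO`.
#' @param tpm_layers Named list of TPM matrices, e.g.
#'   `list(metagenome = mg, metatranscriptome = mt)`.
#' @return A `data.table` with columns `sample`, `layer`, `subunit`, `ko`,
#'   `present`.
#' @export
nitrogenase_screen <- function(annotations, tpm_layers) {
  stopifnot(is.list(tpm_layers), !is.null(names(tpm_layers)))
  res <- list()
  for (layer in names(tpm_layers)) {
    tpm <- tpm_layers[[layer]]
    pres <- present_kos(tpm, annotations)
    for (s in rownames(tpm)) {
      res[[length(res) + 1L]] <- data.table::data.table(
        sample = s,
        layer = layer,
        subunit = names(NITROGENASE_KOS),
        ko = unname(NITROGENASE_KOS),
        present = unname(NITROGENASE_KOS) %in% pres[[s]]
      )
    }
  }
  data.table::rbindlist(res)
}
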