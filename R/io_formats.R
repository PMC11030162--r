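# Readers and writers for every external table the pipeline touches.
# All tabular IO goes through data.table; every reader validates its contract
# and fails with the offending line/field named.

BLAST6_COLS <- c(
  "query_id", "subject_id", "percent_identity", "align_length", "mismatches",
  "gap_opens", "qstart", "qend", "sstart", "send", "evalue", "bitscore"
)

#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Parses the standard 12-column tab-separated BLAST output. Row order is
#' preserved; no header line is expected. Coordinates are kept as read
#' (1-based inclusive) and are never used arithmetically downstream -- only
#' `bitscore`, `evalue` and `subject_id` feed best-hit taxonomy.
#'
#' @param path Path to a tab-separated file with exactly 12 columns per row.
#' @return A `data.table` with columns `query_id`, `subject_id`,
#'   `percent_identity`, `align_length`, `mismatches`, `gap_opens`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`. Empty file gives zero rows.
#' @export
read_blast6 <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.table::as.data.table(
      stats::setNames(
        c(
          list(character(), character()),
          rep(list(numeric()), 10L)
        ),
        BLAST6_COLS
      )
    )
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad) > 0L) {
    stop(sprintf(
      "read_blast6: line %d has %d columns, expected 12", bad[1L], nf[bad[1L]]
    ), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  out <- data.table::data.table(
    query_id = m[, 1L], subject_id = m[, 2L]
  )
  num_cols <- BLAST6_COLS[3:12]
  for (j in seq_along(num_cols)) {
    v <- suppressWarnings(as.numeric(m[, j + 2L]))
    if (anyNA(v)) {
      stop(sprintf(
        "read_blast6: non-numeric value '%s' in column %s at line %d",
        m[which(is.na(v))[1L], j + 2L], num_cols[j], which(is.na(v))[1L]
      ), call. = FALSE)
    }
    data.table::set(out, j = num_cols[j], value = v)
  }
  if (any(out$bitscore < 0)) {
    stop("read_blast6: negative bitscore", call. = FALSE)
  }
  if (any(out$evalue < 0)) {
    stop("read_blast6: negative evalue", call. = FALSE)
  }
  out[]
}

#' Read gene lengths from a FASTA file
#'
#' Record ids are taken up to the first whitespace and must be unique. The
#' length of a record is the number of sequence characters over all of its
#' (possibly wrapped) lines. Lengths are returned in bp; the TPM computation
#' consumes bp directly (the kb conversion cancels in the ratio).
#'
#' @param path Path to a FASTA file.
#' @return Named integer vector `gene_id -> length_bp`.
#' @export
read_fasta_lengths <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  hdr <- startsWith(lines, ">")
  if (!any(hdr)) {
    if (all(!nzchar(lines))) {
      return(stats::setNames(integer(0), character(0)))
    }
    stop("read_fasta_lengths: no FASTA headers found", call. = FALSE)
  }
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  if (anyDuplicated(ids)) {
    stop(sprintf(
      "read_fasta_lengths: duplicate record id '%s'",
      ids[duplicated(ids)][1L]
    ), call. = FALSE)
  }
  rec <- cumsum(hdr)
  seq_lines <- !hdr & nzchar(lines)
  widths <- nchar(gsub("\\s", "", lines))
  len <- vapply(seq_along(ids), function(i) {
    sum(widths[seq_lines & rec == i])
  }, integer(1))
  if (any(len == 0L)) {
    stop(sprintf(
      "read_fasta_lengths: empty sequence for record '%s'",
      ids[len == 0L][1L]
    ), call. = FALSE)
  }
  stats::setNames(len, ids)
}

#' Read a KEGG module flat file
#'
#' Records are delimited by `///`. Each record must carry `ENTRY` and
#' `DEFINITION` lines; a DEFINITION spanning several lines (continuation lines
#' are indented, with no keyword) is joined with single spaces.
#'
#' @param path Path to a KEGG module flat file.
#' @return A `data.table` with columns `module_id`, `name`, `definition`.
#' @export
read_module_flatfile <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  recs <- split(lines, cumsum(c(0L, utils::head(lines == "///", -1L))))
  out <- lapply(recs, function(rl) {
    rl <- rl[rl != "///" & nzchar(rl)]
    if (length(rl) == 0L) return(NULL)
    kw <- sub("^([A-Z_]+)\\s.*$", "\\1", rl)
    kw[!grepl("^[A-Z_]+\\s", rl)] <- ""  # continuation lines
    entry_i <- which(kw == "ENTRY")
    if (length(entry_i) == 0L) {
      stop("read_module_flatfile: record without ENTRY line", call. = FALSE)
    }
    module_id <- regmatches(
      rl[entry_i[1L]], regexpr("M\\d{5}", rl[entry_i[1L]])
    )
    if (length(module_id) == 0L) {
      stop(sprintf(
        "read_module_flatfile: no M##### accession in ENTRY line '%s'",
        rl[entry_i[1L]]
      ), call. = FALSE)
    }
    name_i <- which(kw == "NAME")
    name <- if (length(name_i) > 0L) {
      trimws(sub("^NAME\\s+", "", rl[name_i[1L]]))
    } else ""
    def_i <- which(kw == "DEFINITION")
    if (length(def_i) == 0L) {
      stop(sprintf(
        "read_module_flatfile: module %s lacks a DEFINITION", module_id
      ), call. = FALSE)
    }
    # collect continuation lines directly following DEFINITION
    parts <- trimws(sub("^DEFINITION\\s+", "", rl[def_i[1L]]))
    i <- def_i[1L] + 1L
    while (i <= length(rl) && kw[i] == "") {
      parts <- c(parts, trimws(rl[i]))
      i <- i + 1L
    }
    definition <- paste(parts, collapse = " ")
    if (!balanced_parens(definition)) {
      stop(sprintf(
        "read_module_flatfile: unbalanced parentheses in DEFINITION of %s",
        module_id
      ), call. = FALSE)
    }
    data.table::data.table(
      module_id = module_id, name = name, definition = definition
    )
  })
  out <- data.table::rbindlist(out)
  if (nrow(out) == 0L) {
    stop("read_module_flatfile: no records found", call. = FALSE)
  }
  out[]
}

balanced_parens <- function(x) {
  chars <- strsplit(x, "")[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  all(depth >= 0L) && (length(depth) == 0L || depth[length(depth)] == 0L)
}

#' Read a KOfam-style annotation table
#'
#' Five tab-separated columns with header: `gene_id`, `ko_id`, `score`,
#' `threshold`, `evalue`. Raw hmmsearch output is out of scope; only the
#' fields the adjudication rule needs are consumed.
#'
#' @param path Path to the TSV.
#' @return A `data.table` with the five columns, types validated.
#' @export
read_kofam <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("gene_id", "ko_id")))
  need <- c("gene_id", "ko_id", "score", "threshold", "evalue")
  if (!all(need %in% names(dt))) {
    stop(sprintf(
      "read_kofam: missing column(s): %s",
      paste(setdiff(need, names(dt)), collapse = ", ")
    ), call. = FALSE)
  }
  bad <- !grepl("^K\\d{5}$", dt$ko_id)
  if (any(bad)) {
    stop(sprintf(
      "read_kofam: invalid KO id '%s'", dt$ko_id[bad][1L]
    ), call. = FALSE)
  }
  if (any(dt$evalue < 0)) stop("read_kofam: negative evalue", call. = FALSE)
  dt[, need, with = FALSE]
}

CAZY_CLASS_PREFIX <- c("GH", "GT", "PL", "CE", "AA", "CBM")

#' Read a dbCAN-style CAZyme annotation table
#'
#' Two tab-separated columns with header: `gene_id`, `cazy_family`. A gene may
#' appear on several rows (one per assigned family). Family labels must begin
#' with one of the CAZy class prefixes (GH, GT, PL, CE, AA, CBM); subfamily
#' suffixes (e.g. `GH5_5`) are allowed and retained.
#'
#' @param path Path to the TSV.
#' @return A `data.table` with columns `gene_id`, `cazy_family`.
#' @export
read_dbcan <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("gene_id", "cazy_family")
  if (!all(need %in% names(dt))) {
    stop("read_dbcan: expected columns gene_id, cazy_family", call. = FALSE)
  }
  ok <- grepl(
    sprintf("^(%s)\\d", paste(CAZY_CLASS_PREFIX, collapse = "|")),
    dt$cazy_family
  )
  if (any(!ok)) {
    stop(sprintf(
      "read_dbcan: invalid CAZy family label '%s'", dt$cazy_family[!ok][1L]
    ), call. = FALSE)
  }
  dt[, need, with = FALSE]
}

#' Read a per-sample gene count matrix
#'
#' TSV with a `gene_id` column followed by one numeric column per sample.
#' Returned as a samples x genes numeric matrix (genes as columns), the
#' orientation used by all downstream operations.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, rownames = samples, colnames = genes.
#' @export
read_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1L] != "gene_id") {
    stop("read_counts: first column must be gene_id", call. = FALSE)
  }
  genes <- dt$gene_id
  if (anyDuplicated(genes)) {
    stop("read_counts: duplicate gene_id rows", call. = FALSE)
  }
  m <- as.matrix(dt[, -1L])
  if (!is.numeric(m)) stop("read_counts: non-numeric counts", call. = FALSE)
  if (any(m < 0)) stop("read_counts: negative counts", call. = FALSE)
  rownames(m) <- genes
  t(m)
}

#' Write a samples x genes matrix as a genes-by-sample TSV
#'
#' Inverse of [read_counts()]: genes become rows under a `gene_id` column.
#'
#' @param m Numeric matrix, rownames = samples, colnames = genes.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(m, path) {
  dt <- data.table::data.table(gene_id = colnames(m))
  for (s in rownames(m)) data.table::set(dt, j = s, value = m[s, ])
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a subject-to-lineage taxonomy map
#'
#' TSV with header `subject_id`, `lineage`; lineage is semicolon-joined,
#' ordered superkingdom;phylum;class;order;family;genus, truncated where
#' unresolved (no internal gaps).
#'
#' @param path Path to the TSV.
#' @return A `data.table` with columns `subject_id` and one column per rank.
#' @export
read_taxmap <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("subject_id", "lineage") %in% names(dt))) {
    stop("read_taxmap: expected columns subject_id, lineage", call. = FALSE)
  }
  cbind(
    dt[, .(subject_id = subject_id)],
    split_lineage(dt$lineage)
  )
}

LINEAGE_RANKS <- c(
  "superkingdom", "phylum", "class", "order", "family", "genus"
)

#' Split semicolon-joined lineage strings into rank columns
#'
#' @param x Character vector of semicolon-joined lineages (possibly truncated).
#' @return A `data.table` with one column per rank in
#'   superkingdom..genus order; absent ranks are `NA`.
#' @export
split_lineage <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  out <- data.table::as.data.table(
    stats::setNames(
      lapply(seq_along(LINEAGE_RANKS), function(i) {
        v <- vapply(parts, function(p) {
          if (length(p) >= i && nzchar(trimws(p[i]))) trimws(p[i])
          else NA_character_
        }, character(1))
        v
      }),
      LINEAGE_RANKS
    )
  )
  reserved <- c("unassigned", "Below 1%")
  for (r in LINEAGE_RANKS) {
    if (any(out[[r]] %in% reserved)) {
      stop(sprintf(
        "split_lineage: reserved label used as a taxon at rank %s", r
      ), call. = FALSE)
    }
  }
  # no gaps: a present rank implies all higher ranks present
  for (i in seq_along(LINEAGE_RANKS)[-1L]) {
    gap <- !is.na(out[[i]]) & is.na(out[[i - 1L]])
    if (any(gap)) {
      stop(sprintf(
        "split_lineage: rank %s present without %s",
        LINEAGE_RANKS[i], LINEAGE_RANKS[i - 1L]
      ), call. = FALSE)
    }
  }
  out
}

#' Join rank columns back into semicolon lineage strings
#'
#' @param lineages A data.frame with the rank columns of [split_lineage()].
#' @return Character vector; fully-`NA` rows give `""`.
#' @export
join_lineage <- function(lineages) {
  m <- as.matrix(as.data.frame(lineages)[, LINEAGE_RANKS, drop = FALSE])
  apply(m, 1L, function(r) paste(r[!is.na(r)], collapse = ";"))
}

#' Read the sample metadata table
#'
#' TSV with header `sample`, `putative_status` (healthy|rotten).
#'
#' @param path Path to the TSV.
#' @return A `data.table` with the two columns.
#' @export
read_metadata <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("sample", "putative_status") %in% names(dt))) {
    stop("read_metadata: expected columns sample, putative_status",
         call. = FALSE)
  }
  bad <- !dt$putative_status %in% c("healthy", "rotten")
  if (any(bad)) {
    stop(sprintf(
      "read_metadata: invalid putative_status '%s'",
      dt$putative_status[bad][1L]
    ), call. = FALSE)
  }
  dt
}

#' Read a gene annotation table
#'
#' TSV with header `gene_id`, `length_bp`, `lineage` (semicolon-joined, may be
#' empty = unassigned), `ko` (empty if none), `cazy_families` (comma-joined,
#' empty if none). This is the denormalized table emitted by the synthetic
#' generator and consumed by the orchestrator.
#'
#' @param path Path to the TSV.
#' @return A `data.table` with those five columns plus the split rank columns.
#' @export
read_annotations <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("gene_id", "length_bp", "lineage", "ko", "cazy_families")
  if (!all(need %in% names(dt))) {
    stop(sprintf(
      "read_annotations: missing column(s): %s",
      paste(setdiff(need, names(dt)), collapse = ", ")
    ), call. = FALSE)
  }
  dt[, length_bp := as.integer(length_bp)]
  cbind(dt[, need, with = FALSE], split_lineage(dt$lineage))
}

#' Write a gene annotation table
#'
#' @param ann A data.frame with columns `gene_id`, `length_bp`, `lineage`,
#'   `ko`, `cazy_families`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(ann, path) {
  need <- c("gene_id", "length_bp", "lineage", "ko", "cazy_families")
  data.table::fwrite(
    data.table::as.data.table(ann)[, need, with = FALSE], path, sep = "\t"
  )
  invisible(path)
}
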