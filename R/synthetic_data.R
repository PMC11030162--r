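# Synthetic fruiting-body community generator.
#
# Emulates the structure of paired metagenome/metatranscriptome gene tables
# from healthy and rotten polypore fruiting bodies: healthy samples dominated
# (~80% of reads) by one focal fungal taxon, rotten samples dominated by a
# diverse bacterial community, KO and CAZyme-family annotations per gene, and
# planted pathway/CAZyme ground truth so recovery can be scored exactly.
# Counts are Dirichlet-multinomial (gene shares proportional to
# length x within-family weight, scaled by the family's condition share).

FOCAL_LINEAGE <- "Eukaryota;Basidiomycota;Agaricomycetes;Polyporales;Polyporaceae;Fomes"

#' Default family table of the synthetic community
#'
#' One row per non-focal family: `family`, semicolon `lineage`, `kind`
#' (bacterial / fungal / arthropod / protist / unassigned) and unnormalized
#' mass weights for healthy and rotten metagenomes. The pseudo-family
#' `"__unassigned__"` models genes with no database hit.
#'
#' @return A `data.table`.
#' @export
default_families <- function() {
  data.table::rbindlist(lapply(list(
    list("Burkholderiaceae", "Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales;Burkholderiaceae", "bacterial", 0.3, 10.7),
    list("Microbacteriaceae", "Bacteria;Actinobacteria;Actinomycetia;Micrococcales;Microbacteriaceae", "bacterial", 1.2, 9.7),
    list("Sphingomonadaceae", "Bacteria;Proteobacteria;Alphaproteobacteria;Sphingomonadales;Sphingomonadaceae", "bacterial", 0.1, 8.2),
    list("Yersiniaceae", "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Yersiniaceae", "bacterial", 0.3, 3.0),
    list("Comamonadaceae", "Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales;Comamonadaceae", "bacterial", 0.1, 3.0),
    list("Rhodanobacteraceae", "Bacteria;Proteobacteria;Gammaproteobacteria;Lysobacterales;Rhodanobacteraceae", "bacterial", 0.05, 2.5),
    list("Bradyrhizobiaceae", "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Bradyrhizobiaceae", "bacterial", 0.05, 2.5),
    list("Xanthobacteraceae", "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Xanthobacteraceae", "bacterial", 0.05, 2.0),
    list("Chitinophagaceae", "Bacteria;Bacteroidetes;Chitinophagia;Chitinophagales;Chitinophagaceae", "bacterial", 0.05, 2.0),
    list("Streptomycetaceae", "Bacteria;Actinobacteria;Actinomycetia;Streptomycetales;Streptomycetaceae", "bacterial", 0.1, 2.0),
    list("Micromonosporaceae", "Bacteria;Actinobacteria;Actinomycetia;Micromonosporales;Micromonosporaceae", "bacterial", 0.05, 2.0),
    list("Acidobacteriaceae", "Bacteria;Acidobacteria;Acidobacteriia;Acidobacteriales;Acidobacteriaceae", "bacterial", 0.05, 1.5),
    list("Myxococcaceae", "Bacteria;Proteobacteria;Deltaproteobacteria;Myxococcales;Myxococcaceae", "bacterial", 0.02, 1.5),
    list("Verrucomicrobiaceae", "Bacteria;Verrucomicrobia;Verrucomicrobiae;Verrucomicrobiales;Verrucomicrobiaceae", "bacterial", 0.02, 1.5),
    list("Hypocreaceae", "Eukaryota;Ascomycota;Sordariomycetes;Hypocreales;Hypocreaceae", "fungal", 0.1, 1.5),
    list("Hyaloscyphaceae", "Eukaryota;Ascomycota;Leotiomycetes;Helotiales;Hyaloscyphaceae", "fungal", 0.05, 1.0),
    list("Cephalothecaceae", "Eukaryota;Ascomycota;Sordariomycetes;Sordariales;Cephalothecaceae", "fungal", 0.05, 1.0),
    list("Helotiaceae", "Eukaryota;Ascomycota;Leotiomycetes;Helotiales;Helotiaceae", "fungal", 0.05, 1.0),
    list("Chaetosphaeriaceae", "Eukaryota;Ascomycota;Sordariomycetes;Chaetosphaeriales;Chaetosphaeriaceae", "fungal", 0.02, 0.8),
    list("Magnaporthaceae", "Eukaryota;Ascomycota;Sordariomycetes;Magnaporthales;Magnaporthaceae", "fungal", 0.3, 0.3),
    list("Kickxellaceae", "Eukaryota;Zoopagomycota;Kickxellomycetes;Kickxellales;Kickxellaceae", "fungal", 0.02, 0.5),
    list("Physaraceae", "Eukaryota;Evosea;Eumycetozoa;Physarales;Physaraceae", "protist", 0.02, 1.0),
    list("Tenebrionidae", "Eukaryota;Arthropoda;Insecta;Coleoptera;Tenebrionidae", "arthropod", 0.02, 2.0),
    list("Cerambycidae", "Eukaryota;Arthropoda;Insecta;Coleoptera;Cerambycidae", "arthropod", 0.01, 0.5),
    list("Chrysomelidae", "Eukaryota;Arthropoda;Insecta;Coleoptera;Chrysomelidae", "arthropod", 0.01, 0.5),
    list("Pyroglyphidae", "Eukaryota;Arthropoda;Arachnida;Sarcoptiformes;Pyroglyphidae", "arthropod", 0.01, 0.5),
    list("Oppiidae", "Eukaryota;Arthropoda;Arachnida;Sarcoptiformes;Oppiidae", "arthropod", 0.01, 0.5),
    list("Acaridae", "Eukaryota;Arthropoda;Arachnida;Sarcoptiformes;Acaridae", "arthropod", 0.01, 0.5),
    list("__unassigned__", "", "unassigned", 2.0, 3.0)
  ), function(x) {
    data.table::data.table(
      family = x[[1]], lineage = x[[2]], kind = x[[3]],
      healthy_weight = x[[4]], rotten_weight = x[[5]]
    )
  }))
}

#' Default planted CAZyme table
#'
#' `family` "focal" denotes the focal taxon. Multi-family genes are written
#' with `+` (one gene carrying both families). The arthropod chitinase
#' counts (13/1/1 GH18 genes in Tenebrionidae/Cerambycidae/Pyroglyphidae) and
#' the beta-glucanase spread mirror the default stated community.
#'
#' @return A `data.table` with `family`, `cazy_family`, `n_genes`.
#' @export
default_planted_cazymes <- function() {
  data.table::rbindlist(lapply(list(
    list("focal", "GH7", 6L), list("focal", "AA9", 4L),
    list("focal", "GH16", 5L), list("focal", "GH18", 4L),
    list("focal", "GH5", 3L), list("focal", "GH47", 2L),
    list("focal", "GH28", 1L),
    list("Tenebrionidae", "GH18", 13L), list("Tenebrionidae", "GH16", 10L),
    list("Cerambycidae", "GH18", 1L),
    list("Pyroglyphidae", "GH18", 1L),
    list("Oppiidae", "GH16", 3L),
    list("Acaridae", "GH16", 2L),
    list("Chrysomelidae", "GH16", 1L),
    list("Micromonosporaceae", "GH16", 4L),
    list("Micromonosporaceae", "GH5+GH18", 1L),
    list("Streptomycetaceae", "GH16", 3L),
    list("Cephalothecaceae", "GH16", 3L),
    list("Chaetosphaeriaceae", "GH16", 3L),
    list("Burkholderiaceae", "GH23", 2L),
    list("Microbacteriaceae", "GH23", 2L),
    list("Sphingomonadaceae", "GH24", 2L),
    list("Chitinophagaceae", "GH26", 2L),
    list("Myxococcaceae", "GH76", 2L),
    list("Acidobacteriaceae", "GH28", 1L),
    list("Physaraceae", "GH33", 2L), list("Physaraceae", "GH38", 1L),
    list("Verrucomicrobiaceae", "GH5", 2L),
    list("Kickxellaceae", "GH6", 1L)
  ), function(x) {
    data.table::data.table(
      family = x[[1]], cazy_family = x[[2]], n_genes = x[[3]]
    )
  }))
}

#' Default planted complete modules per family
#'
#' @return Named list `family -> character vector of module ids` planted with
#'   their full (non-optional) KO set. The nitrogen-fixation module is
#'   planted in Bradyrhizobiaceae but its KOs are blacklisted by the default
#'   `omit_kos`, so it stays incomplete unless the blacklist is lifted.
#' @export
default_planted_modules <- function() {
  list(
    Burkholderiaceae = c("M00530", "M00531"),
    Yersiniaceae = "M00530",
    Comamonadaceae = "M00530",
    Rhodanobacteraceae = "M00530",
    Bradyrhizobiaceae = c("M00530", "M00175"),
    Microbacteriaceae = c("M00176", "M00345"),
    Sphingomonadaceae = c("M00176", "M00597"),
    Streptomycetaceae = "M00378",
    Xanthobacteraceae = c("M00935", "M00531")
  )
}

#' Default planted partial KO sets per family
#'
#' Splits the denitrification module across two families so that it is
#' complete for the pooled bacterial community but incomplete in every single
#' family.
#'
#' @return Named list `family -> KO vector`.
#' @export
default_planted_kos <- function() {
  list(
    Burkholderiaceae = c("K00370", "K00371", "K00374", "K00368"),
    Comamonadaceae = c("K04561", "K02305", "K00376")
  )
}

#' Build a community specification
#'
#' The defaults are the stated world every test runs against: one focal
#' fungal taxon at 80% of healthy metagenome reads and 0.1% of rotten reads,
#' a bacteria-dominated rotten community, nitrogenase subunit KOs
#' blacklisted, and arthropod chitinase/beta-glucanase transcripts
#' concentrated in the rotten metatranscriptome.
#'
#' @param focal_label Genus-level label of the focal taxon.
#' @param families Family table, see [default_families()].
#' @param healthy_focal_share,rotten_focal_share Focal fraction of expected
#'   metagenome reads per condition (defaults 0.80 and 0.001).
#' @param genes_per_family Genes simulated per non-focal family (default 40).
#' @param focal_genes Genes simulated for the focal taxon (default 300).
#' @param unassigned_genes Genes with no database hit (default 60).
#' @param depth Reads per metagenome sample (default 1e5).
#' @param mt_depth Reads per metatranscriptome sample (default `depth`).
#' @param overdispersion Dirichlet-multinomial overdispersion; 0 gives pure
#'   multinomial sampling. The default 0.001 (concentration 1000) puts the
#'   sd of the healthy focal share near 0.013, consistent with the stated
#'   world in which healthy samples sit within +-0.05 of an 0.80 focal share
#'   at depth 1e5.
#' @param planted_modules,planted_kos,planted_cazymes Ground-truth planting,
#'   see the corresponding `default_*()` helpers.
#' @param omit_kos Global KO blacklist (default the nitrogenase subunits
#'   K02588, K02586, K02591).
#' @param unassigned_fraction Fraction of rotten metatranscriptome reads from
#'   unassignable genes (default 0.5; a free choice, the source data only
#'   states that most rotten transcription is unassigned).
#' @param mt_focal_caz_boost Expression multiplier of focal CAZyme genes in
#'   the metatranscriptome (default 5: the living fungus actively remodels
#'   its cell wall).
#' @param mt_nonfocal_caz_damp Multiplier of non-focal CAZyme genes in
#'   *healthy* metatranscriptomes (default 0.2: bystander taxa are largely
#'   inactive in living fruiting bodies).
#' @param mt_arthropod_caz_boost Within-family multiplier of arthropod
#'   chitinase / beta-glucanase genes in *rotten* metatranscriptomes
#'   (default 50: nearly all of an arthropod family's transcription is its
#'   planted CAZymes).
#' @param mt_arthropod_family_boost Family-share multiplier of arthropod
#'   families in *rotten* metatranscriptomes (default 15, chosen so the
#'   decomposer fauna carries the majority of rotten CAZyme transcription).
#' @return A `community_spec` list, validated.
#' @export
community_spec <- function(focal_label = "Fomes",
                           families = default_families(),
                           healthy_focal_share = 0.80,
                           rotten_focal_share = 0.001,
                           genes_per_family = 40L,
                           focal_genes = 300L,
                           unassigned_genes = 60L,
                           depth = 1e5,
                           mt_depth = depth,
                           overdispersion = 0.001,
                           planted_modules = default_planted_modules(),
                           planted_kos = default_planted_kos(),
                           planted_cazymes = default_planted_cazymes(),
                           omit_kos = c("K02588", "K02586", "K02591"),
                           unassigned_fraction = 0.5,
                           mt_focal_caz_boost = 5,
                           mt_nonfocal_caz_damp = 0.2,
                           mt_arthropod_caz_boost = 50,
                           mt_arthropod_family_boost = 15) {
  stopifnot(
    healthy_focal_share >= 0, healthy_focal_share <= 1,
    rotten_focal_share >= 0, rotten_focal_share <= 1,
    depth >= 1, mt_depth >= 1, overdispersion >= 0,
    unassigned_fraction >= 0, unassigned_fraction < 1
  )
  families <- data.table::as.data.table(families)
  bad <- setdiff(unlist(planted_modules), packaged_modules()$module_id)
  if (length(bad) > 0L) {
    stop(sprintf(
      "community_spec: planted module '%s' not in the packaged module file",
      bad[1L]
    ), call. = FALSE)
  }
  unknown <- setdiff(
    c(names(planted_modules), names(planted_kos),
      setdiff(planted_cazymes$family, "focal")),
    families$family
  )
  if (length(unknown) > 0L) {
    stop(sprintf(
      "community_spec: planted family '%s' not in the family table",
      unknown[1L]
    ), call. = FALSE)
  }
  structure(list(
    focal_label = focal_label,
    focal_lineage = FOCAL_LINEAGE,
    families = families,
    healthy_focal_share = healthy_focal_share,
    rotten_focal_share = rotten_focal_share,
    genes_per_family = as.integer(genes_per_family),
    focal_genes = as.integer(focal_genes),
    unassigned_genes = as.integer(unassigned_genes),
    depth = depth,
    mt_depth = mt_depth,
    overdispersion = overdispersion,
    planted_modules = planted_modules,
    planted_kos = planted_kos,
    planted_cazymes = data.table::as.data.table(planted_cazymes),
    omit_kos = omit_kos,
    unassigned_fraction = unassigned_fraction,
    mt_focal_caz_boost = mt_focal_caz_boost,
    mt_nonfocal_caz_damp = mt_nonfocal_caz_damp,
    mt_arthropod_caz_boost = mt_arthropod_caz_boost,
    mt_arthropod_family_boost = mt_arthropod_family_boost
  ), class = "community_spec")
}

packaged_modules <- function() {
  read_module_flatfile(
    system.file("extdata", "modules_synthetic.txt", package = "fbmeta")
  )
}

packaged_ko_repertoire <- function() {
  data.table::fread(
    system.file("extdata", "ko_repertoire.tsv", package = "fbmeta"),
    sep = "\t", header = TRUE
  )
}

# --- internal gene table -----------------------------------------------------

# Builds the per-gene table: family, lineage, length, within-family weight,
# KO, CAZy families. Consumes RNG state (lengths, weights, filler KOs).
build_gene_table <- function(spec) {
  modules <- packaged_modules()
  repertoire <- packaged_ko_repertoire()
  housekeeping <- repertoire$ko[repertoire$role == "housekeeping"]
  housekeeping <- setdiff(housekeeping, spec$omit_kos)

  fam_rows <- rbind(
    data.table::data.table(
      family = "focal", lineage = spec$focal_lineage, kind = "focal",
      n_genes = spec$focal_genes
    ),
    data.table::data.table(
      family = spec$families$family,
      lineage = spec$families$lineage,
      kind = spec$families$kind,
      n_genes = ifelse(spec$families$family == "__unassigned__",
                       spec$unassigned_genes, spec$genes_per_family)
    )
  )

  genes <- list()
  for (i in seq_len(nrow(fam_rows))) {
    fam <- fam_rows$family[i]
    n <- fam_rows$n_genes[i]
    ko <- rep("", n)
    caz <- rep("", n)
    slot <- 1L

    if (fam_rows$kind[i] != "unassigned") {
      # planted CAZymes
      pc <- spec$planted_cazymes[family == fam]
      for (j in seq_len(nrow(pc))) {
        for (g in seq_len(pc$n_genes[j])) {
          if (slot > n) stop(sprintf(
            "build_gene_table: family %s needs more gene slots", fam
          ), call. = FALSE)
          caz[slot] <- gsub("+", ",", pc$cazy_family[j], fixed = TRUE)
          slot <- slot + 1L
        }
      }
      # planted complete modules: one gene per (non-blacklisted) KO
      planted <- spec$planted_modules[[fam]]
      kos_needed <- character(0)
      for (m in planted) {
        expr <- parse_definition(
          modules$definition[modules$module_id == m]
        )
        kos_needed <- union(kos_needed, module_kos(expr,
                                                   include_optional = FALSE))
      }
      kos_needed <- union(kos_needed, spec$planted_kos[[fam]])
      kos_needed <- setdiff(kos_needed, spec$omit_kos)
      for (k in kos_needed) {
        if (slot > n) stop(sprintf(
          "build_gene_table: family %s needs more gene slots", fam
        ), call. = FALSE)
        ko[slot] <- k
        slot <- slot + 1L
      }
      # fill: ~60% of remaining genes get a housekeeping KO
      if (slot <= n) {
        rest <- slot:n
        take <- rest[stats::runif(length(rest)) < 0.6]
        ko[take] <- sample(housekeeping, length(take), replace = TRUE)
      }
    }
    genes[[i]] <- data.table::data.table(
      gene_id = sprintf("%s_g%03d", gsub("_", "", fam), seq_len(n)),
      family_key = fam,
      lineage = fam_rows$lineage[i],
      kind = fam_rows$kind[i],
      ko = ko,
      cazy_families = caz
    )
  }
  genes <- data.table::rbindlist(genes)
  # lengths log-normal, clipped to [150, 30000] bp
  len <- round(stats::rlnorm(nrow(genes), meanlog = log(1000), sdlog = 0.6))
  genes[, length_bp := as.integer(pmin(pmax(len, 150), 30000))]
  genes[, weight := stats::rlnorm(.N, meanlog = 0, sdlog = 0.5)]
  genes[]
}

# expected per-family share vector for a condition
family_shares <- function(spec, condition) {
  w <- if (condition == "healthy") spec$families$healthy_weight
       else spec$families$rotten_weight
  focal <- if (condition == "healthy") spec$healthy_focal_share
           else spec$rotten_focal_share
  shares <- c(focal, (1 - focal) * w / sum(w))
  stats::setNames(shares, c("focal", spec$families$family))
}

# gene-level base probabilities for one sample
gene_probs <- function(genes, shares, expr_mult = NULL) {
  w <- genes$length_bp * genes$weight
  if (!is.null(expr_mult)) w <- w * expr_mult
  p <- numeric(nrow(genes))
  for (fam in names(shares)) {
    idx <- genes$family_key == fam
    tot <- sum(w[idx])
    if (tot > 0) p[idx] <- shares[[fam]] * w[idx] / tot
  }
  p / sum(p)
}

# MT expression multipliers for one condition
mt_multipliers <- function(spec, genes, condition) {
  mult <- rep(1, nrow(genes))
  is_caz <- nzchar(genes$cazy_families)
  focal <- genes$family_key == "focal"
  arth <- genes$kind == "arthropod"
  mult[is_caz & focal] <- spec$mt_focal_caz_boost
  if (condition == "healthy") {
    mult[is_caz & !focal] <- spec$mt_nonfocal_caz_damp
  } else {
    mult[is_caz & arth] <- spec$mt_arthropod_caz_boost
  }
  mult
}

# MT family shares. Rotten samples: arthropod families are boosted (the
# decomposer fauna dominates transcription), then unassigned_fraction of the
# reads is pushed onto the unassigned pseudo-family.
mt_family_shares <- function(spec, condition) {
  shares <- family_shares(spec, condition)
  if (condition != "healthy") {
    arth <- spec$families$family[spec$families$kind == "arthropod"]
    shares[arth] <- shares[arth] * spec$mt_arthropod_family_boost
    u <- spec$unassigned_fraction
    rest <- setdiff(names(shares), "__unassigned__")
    shares[rest] <- shares[rest] / sum(shares[rest]) * (1 - u)
    shares[["__unassigned__"]] <- u
  }
  shares / sum(shares)
}

# one Dirichlet-multinomial draw
draw_counts <- function(p, depth, overdispersion) {
  if (overdispersion > 0) {
    alpha <- p / overdispersion
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(g) == 0) g <- p  # degenerate fallback
    p <- g / sum(g)
  }
  as.vector(stats::rmultinom(1L, size = depth, prob = p))
}

#' Generate a synthetic paired metagenome/metatranscriptome dataset
#'
#' All randomness flows from `seed`; identical `(spec, seed)` produce
#' identical outputs.
#'
#' @param spec A [community_spec()].
#' @param n_healthy,n_rotten Number of samples per condition (total >= 2).
#' @param seed RNG seed.
#' @return A `synthetic_dataset` list: `annotations` (gene table with
#'   lineage/KO/CAZyme columns), `mg_counts` and `mt_counts`
#'   (samples x genes), `truth` (condition labels, expected family shares,
#'   planted modules/KOs/CAZymes, omit list), plus internal `genes` and
#'   `spec` needed by [make_transitional()].
#' @export
generate_community <- function(spec = community_spec(), n_healthy = 5L,
                               n_rotten = 5L, seed = 42L) {
  stopifnot(inherits(spec, "community_spec"))
  if (n_healthy + n_rotten < 2L) {
    stop("generate_community: need at least 2 samples for clustering",
         call. = FALSE)
  }
  set.seed(seed)
  genes <- build_gene_table(spec)

  samples <- c(
    if (n_healthy > 0L) sprintf("H%02d", seq_len(n_healthy)),
    if (n_rotten > 0L) sprintf("R%02d", seq_len(n_rotten))
  )
  condition <- stats::setNames(
    c(rep("healthy", n_healthy), rep("rotten", n_rotten)), samples
  )

  mg <- matrix(0, nrow = length(samples), ncol = nrow(genes),
               dimnames = list(samples, genes$gene_id))
  mt <- mg
  share_rows <- list()
  for (s in samples) {
    cond <- condition[[s]]
    sh_mg <- family_shares(spec, cond)
    p_mg <- gene_probs(genes, sh_mg)
    mg[s, ] <- draw_counts(p_mg, spec$depth, spec$overdispersion)
    sh_mt <- mt_family_shares(spec, cond)
    p_mt <- gene_probs(genes, sh_mt, mt_multipliers(spec, genes, cond))
    mt[s, ] <- draw_counts(p_mt, spec$mt_depth, spec$overdispersion)
    share_rows[[s]] <- sh_mg
  }
  truth <- list(
    condition = condition,
    family_shares = do.call(rbind, share_rows),
    planted_modules = spec$planted_modules,
    planted_kos = spec$planted_kos,
    planted_cazymes = spec$planted_cazymes,
    omit_kos = spec$omit_kos
  )
  annotations <- cbind(
    genes[, .(gene_id, length_bp, lineage, ko, cazy_families)],
    split_lineage(genes$lineage)
  )
  structure(list(
    annotations = annotations,
    mg_counts = mg,
    mt_counts = mt,
    truth = truth,
    genes = genes,
    spec = spec
  ), class = "synthetic_dataset")
}

#' Rewrite one sample as a transitional fruiting body
#'
#' Redraws the sample's count columns with the metagenome focal share set to
#' `mg_focal_share` and the metatranscriptome focal share to
#' `mt_focal_share` (healthy-style expression weights in both layers), and
#' records condition `"transitional"` in the truth table. Models a fruiting
#' body whose DNA profile is already bacteria-rich while the focal fungus is
#' still transcriptionally active (or not).
#'
#' @param dataset A `synthetic_dataset` from [generate_community()].
#' @param sample Sample id to rewrite.
#' @param mg_focal_share,mt_focal_share Target focal fractions in `[0, 1]`.
#' @param seed RNG seed for the redraw.
#' @return The modified dataset.
#' @export
make_transitional <- function(dataset, sample, mg_focal_share,
                              mt_focal_share, seed = 1L) {
  stopifnot(inherits(dataset, "synthetic_dataset"),
            sample %in% rownames(dataset$mg_counts),
            mg_focal_share >= 0, mg_focal_share <= 1,
            mt_focal_share >= 0, mt_focal_share <= 1)
  spec <- dataset$spec
  genes <- dataset$genes
  set.seed(seed)
  retarget <- function(shares, focal) {
    rest <- setdiff(names(shares), "focal")
    shares[rest] <- shares[rest] / sum(shares[rest]) * (1 - focal)
    shares[["focal"]] <- focal
    shares
  }
  sh_mg <- retarget(family_shares(spec, "rotten"), mg_focal_share)
  p_mg <- gene_probs(genes, sh_mg)
  dataset$mg_counts[sample, ] <-
    draw_counts(p_mg, spec$depth, spec$overdispersion)
  sh_mt <- retarget(family_shares(spec, "rotten"), mt_focal_share)
  p_mt <- gene_probs(genes, sh_mt, mt_multipliers(spec, genes, "healthy"))
  dataset$mt_counts[sample, ] <-
    draw_counts(p_mt, spec$mt_depth, spec$overdispersion)
  dataset$truth$condition[[sample]] <- "transitional"
  dataset
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' Emits `annotations.tsv`, `mg_counts.tsv`, `mt_counts.tsv`,
#' `metadata.tsv`, `kofam.tsv`, `dbcan.tsv`, `taxmap.tsv`, `blast6.tsv`
#' and (optionally) `genes.fasta` -- exactly the formats the readers in this
#' package consume. The BLAST table carries, per assigned gene, a best hit to
#' its own family's reference subject plus decoy hits at lower bitscores; the
#' KOfam table includes failing decoy rows (low score or high e-value) so the
#' adjudication filter is exercised on real input.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @param fasta Also write random-nucleotide sequences of the stated lengths
#'   (default TRUE).
#' @param putative Optional named vector overriding the putative field labels
#'   written to `metadata.tsv` (defaults to the truth, with transitional
#'   samples labelled healthy).
#' @param seed Seed for decoy-hit randomness.
#' @return Invisibly, the directory path.
#' @export
write_dataset <- function(dataset, dir, fasta = TRUE, putative = NULL,
                          seed = 7L) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  ann <- dataset$annotations
  write_annotations(ann, file.path(dir, "annotations.tsv"))
  write_counts(dataset$mg_counts, file.path(dir, "mg_counts.tsv"))
  write_counts(dataset$mt_counts, file.path(dir, "mt_counts.tsv"))

  if (is.null(putative)) {
    putative <- ifelse(dataset$truth$condition == "rotten",
                       "rotten", "healthy")
    names(putative) <- names(dataset$truth$condition)
  }
  data.table::fwrite(
    data.table::data.table(sample = names(putative),
                           putative_status = unname(putative)),
    file.path(dir, "metadata.tsv"), sep = "\t"
  )

  # KOfam table with passing rows plus decoys
  has_ko <- ann[nzchar(ko)]
  kofam <- data.table::data.table(
    gene_id = has_ko$gene_id, ko_id = has_ko$ko,
    score = 150, threshold = 100, evalue = 1e-10
  )
  n_decoy <- max(1L, nrow(kofam) %/% 10L)
  decoy_genes <- sample(ann$gene_id, n_decoy)
  decoys <- data.table::data.table(
    gene_id = decoy_genes,
    ko_id = sample(
      setdiff(packaged_ko_repertoire()$ko, dataset$spec$omit_kos),
      n_decoy, replace = TRUE
    ),
    score = c(50, 150)[1L + (seq_len(n_decoy) %% 2L)],
    threshold = 100,
    evalue = c(1e-10, 1e-3)[1L + (seq_len(n_decoy) %% 2L)]
  )
  # decoys alternate failing the score or the e-value condition
  decoys[score > threshold, evalue := 1e-3]
  data.table::fwrite(rbind(kofam, decoys), file.path(dir, "kofam.tsv"),
                     sep = "\t")

  has_caz <- ann[nzchar(cazy_families)]
  dbcan <- has_caz[, .(cazy_family = strsplit(cazy_families, ",")[[1L]]),
                   by = gene_id]
  data.table::fwrite(dbcan, file.path(dir, "dbcan.tsv"), sep = "\t")

  # taxonomy: one reference subject per family + blast6 hits
  fams <- unique(ann[nzchar(lineage), .(lineage)])
  fams[, subject_id := sprintf("ref_%03d", .I)]
  data.table::fwrite(
    fams[, .(subject_id, lineage)], file.path(dir, "taxmap.tsv"), sep = "\t"
  )
  assigned <- ann[nzchar(lineage)]
  best <- merge(assigned, fams, by = "lineage", sort = FALSE)
  hits <- data.table::data.table(
    query_id = best$gene_id, subject_id = best$subject_id,
    percent_identity = 98.5, align_length = best$length_bp %/% 3L,
    mismatches = 1L, gap_opens = 0L,
    qstart = 1L, qend = best$length_bp %/% 3L,
    sstart = 1L, send = best$length_bp %/% 3L,
    evalue = 1e-50, bitscore = 500
  )
  n_dec <- nrow(best)
  decoy_hits <- data.table::copy(hits)
  decoy_hits[, subject_id := sample(fams$subject_id, n_dec, replace = TRUE)]
  decoy_hits[, bitscore := stats::runif(n_dec, 50, 400)]
  decoy_hits[, evalue := 1e-20]
  all_hits <- rbind(hits, decoy_hits)
  data.table::setorder(all_hits, query_id, -bitscore)
  data.table::fwrite(all_hits, file.path(dir, "blast6.tsv"), sep = "\t",
                     col.names = FALSE)

  if (fasta) {
    con <- file(file.path(dir, "genes.fasta"), "w")
    on.exit(close(con))
    for (i in seq_len(nrow(ann))) {
      writeLines(paste0(">", ann$gene_id[i]), con)
      writeLines(paste(
        sample(c("A", "C", "G", "T"), ann$length_bp[i], replace = TRUE),
        collapse = ""
      ), con)
    }
  }
  invisible(dir)
}
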