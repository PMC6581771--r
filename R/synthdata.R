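# Deterministic, seedable generator of complete pipeline inputs with known
# ground truth. The packaged scenario mirrors the study design: four
# pedigrees with affected parent-child pairs, three planted causal variants
# (a FLT1-like c.603A>T missense, a VEGFB-like c.322A>C missense and an
# ITGA2-like c.502+1G>A splice-donor variant, carried as in the published
# family table), three decoy genes shared between two families each,
# background variation largely covered by the known-variant database, an
# expression cohort of 7 cases vs 5 controls with 1117 planted DE genes
# overlapping the candidate genes in exactly 22, and a focal-adhesion-like
# pathway containing the three causal genes.

NON_STOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                           c("TAA", "TAG", "TGA"))

#' Transmit one genotype from two parents
#'
#' Draws one allele from each parent uniformly (Mendelian transmission) and
#' returns the unphased child genotype. Uses the current RNG state.
#'
#' @param parent1_gt,parent2_gt Parent genotypes as `"0/0"`, `"0/1"` or
#'   `"1/1"`.
#' @return Child genotype string.
#' @export
mendelian_transmit <- function(parent1_gt, parent2_gt) {
  dose <- c("0/0" = 0, "0/1" = 1, "1/1" = 2)
  draw <- function(gt) {
    d <- unname(dose[gt])
    if (length(d) != 1 || is.na(d)) {
      abort(paste0("invalid parental genotype: ", gt))
    }
    stats::rbinom(1, 1, d / 2)
  }
  c("0/0", "0/1", "1/1")[draw(parent1_gt) + draw(parent2_gt) + 1]
}

#' The packaged four-family pedigree
#'
#' Three nuclear trios with an affected mother-child pair, plus one
#' 12-member extended family with two sibships (an affected founder, two
#' affected sibs, an affected married-in mother, and three affected
#' grandchildren), matching the study's family structure.
#'
#' @return Pedigree tibble (parents listed before their children).
#' @export
paper_pedigree <- function() {
  trio <- function(f) {
    tibble(
      family_id = f,
      individual_id = paste0(f, c("-FA", "-MO", "-CH")),
      father_id = c(NA, NA, paste0(f, "-FA")),
      mother_id = c(NA, NA, paste0(f, "-MO")),
      sex = c(1L, 2L, 1L),
      affected = c(FALSE, TRUE, TRUE)
    )
  }
  f4 <- tibble(
    family_id = "F4",
    individual_id = paste0("F4-", c("I1", "I2", "II9", "II4", "II3", "II5",
                                    "II8", "III3", "III4", "III7", "III8",
                                    "III9")),
    father_id = paste0("F4-", c(NA, NA, NA, NA, "I1", "I1", "I1", "II3",
                                "II3", "II8", "II8", "II8")),
    mother_id = paste0("F4-", c(NA, NA, NA, NA, "I2", "I2", "I2", "II4",
                                "II4", "II9", "II9", "II9")),
    sex = c(1L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 2L, 2L, 1L, 2L),
    affected = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE,
                 TRUE, TRUE, FALSE)
  )
  f4$father_id[f4$father_id == "F4-NA"] <- NA
  f4$mother_id[f4$mother_id == "F4-NA"] <- NA
  validate_pedigree(bind_rows(trio("F1"), trio("F2"), trio("F3"), f4))
}

#' Scenario configuration
#'
#' Defaults define the packaged study-like scenario: four pedigrees, 300
#' background variants with 95% known-database coverage, 1000 gene models,
#' a 20,000-gene expression cohort of 7 cases vs 5 controls with 1117
#' planted DE genes (mean shift `deg_shift` times the within-group SD), a
#' 22-gene candidate/DEG overlap, and a 5-gene focal-adhesion-like set among
#' 5 gene sets.
#'
#' @param seed Integer master seed; every emitted file draws from its own
#'   derived stream.
#' @param n_background_variants Background variant sites across the toy
#'   genome.
#' @param known_db_coverage Fraction of intergenic background variants
#'   placed in the known-variant set (coding background variants are always
#'   known; see the methods vignette).
#' @param background_maf Founder alternate-allele frequency for background
#'   variants.
#' @param n_gene_models Number of transcript models (>= 150).
#' @param n_expression_genes Genes in the expression matrix (includes all
#'   model genes).
#' @param n_deg Planted differentially expressed genes.
#' @param deg_shift Case-group mean shift in units of `within_group_sd`.
#' @param within_group_sd Within-group SD of expression values (log2 scale).
#' @param n_cases,n_controls Expression cohort sizes.
#' @param candidate_deg_overlap Genes shared between the candidate list and
#'   the DE list (>= 3; includes the three causal genes).
#' @param n_decoy_sets,decoy_set_size Additional gene sets of background
#'   genes.
#' @param focal_extra Non-candidate genes padding the focal set.
#' @param plant_causal,plant_decoy_shared,plant_negative_decoys Toggle the
#'   planted variant groups.
#' @return Validated list of class `famseg_scenario_config`.
#' @export
scenario_config <- function(seed = 42L,
                            n_background_variants = 300L,
                            known_db_coverage = 0.95,
                            background_maf = 0.2,
                            n_gene_models = 1000L,
                            n_expression_genes = 20000L,
                            n_deg = 1117L,
                            deg_shift = 100,
                            within_group_sd = 0.1,
                            n_cases = 7L,
                            n_controls = 5L,
                            candidate_deg_overlap = 22L,
                            n_decoy_sets = 4L,
                            decoy_set_size = 25L,
                            focal_extra = 2L,
                            plant_causal = TRUE,
                            plant_decoy_shared = TRUE,
                            plant_negative_decoys = TRUE) {
  cfg <- list(seed = as.integer(seed),
              n_background_variants = as.integer(n_background_variants),
              known_db_coverage = known_db_coverage,
              background_maf = background_maf,
              n_gene_models = as.integer(n_gene_models),
              n_expression_genes = as.integer(n_expression_genes),
              n_deg = as.integer(n_deg),
              deg_shift = deg_shift,
              within_group_sd = within_group_sd,
              n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              candidate_deg_overlap = as.integer(candidate_deg_overlap),
              n_decoy_sets = as.integer(n_decoy_sets),
              decoy_set_size = as.integer(decoy_set_size),
              focal_extra = as.integer(focal_extra),
              plant_causal = isTRUE(plant_causal),
              plant_decoy_shared = isTRUE(plant_decoy_shared),
              plant_negative_decoys = isTRUE(plant_negative_decoys))
  if (cfg$candidate_deg_overlap < 3) {
    abort("candidate_deg_overlap must be >= 3 (the three causal genes)")
  }
  if (cfg$n_deg < cfg$candidate_deg_overlap) {
    abort("n_deg must be at least candidate_deg_overlap")
  }
  n_named <- 6L + (cfg$candidate_deg_overlap - 3L) + 7L + cfg$focal_extra
  need <- n_named + cfg$n_decoy_sets * cfg$decoy_set_size + 20L
  if (cfg$n_gene_models < max(150L, need)) {
    abort(sprintf("n_gene_models must be >= %d for this configuration",
                  max(150L, need)))
  }
  if (cfg$n_expression_genes < cfg$n_gene_models + cfg$n_deg) {
    abort("n_expression_genes too small for models plus DE genes")
  }
  if (cfg$known_db_coverage < 0 || cfg$known_db_coverage > 1) {
    abort("known_db_coverage must lie in [0, 1]")
  }
  structure(cfg, class = c("famseg_scenario_config", "list"))
}

# gene symbol blocks used by the generator
scenario_genes <- function(cfg) {
  n_filler <- cfg$candidate_deg_overlap - 3L
  list(
    causal = c("FLT1", "VEGFB", "ITGA2"),
    decoy_shared = c("KCNG4", "NCOA6", "KIAA1217"),
    filler = if (n_filler > 0) sprintf("OVLP%02d", seq_len(n_filler))
             else character(),
    negative = sprintf("DCY%02d", 1:7),
    focal_extra = if (cfg$focal_extra > 0) sprintf("FOC%02d",
                                                   seq_len(cfg$focal_extra))
                  else character()
  )
}

# random stop-free CDS of n codons with fixed codon overrides
random_cds <- function(n_codons, overrides = NULL) {
  codons <- sample(NON_STOP_CODONS, n_codons, replace = TRUE)
  for (idx in names(overrides)) codons[as.integer(idx)] <- overrides[[idx]]
  paste(codons, collapse = "")
}

# lay out transcript models across 5 toy chromosomes (4 kb slots)
build_models <- function(cfg) {
  gs <- scenario_genes(cfg)
  named <- c(gs$causal, gs$decoy_shared, gs$filler, gs$negative,
             gs$focal_extra)
  n_bg <- cfg$n_gene_models - length(named)
  genes <- c(named, sprintf("BG%04d", seq_len(n_bg)))
  overrides <- list(
    FLT1 = list(`201` = "GAA"), VEGFB = list(`108` = "AGC"),
    KCNG4 = list(`50` = "GAA", `60` = "GAA"),
    NCOA6 = list(`50` = "GAA", `60` = "GAA"),
    KIAA1217 = list(`50` = "GAA")
  )
  for (g in c(gs$filler, gs$negative)) overrides[[g]] <- list(`50` = "GAA")
  per_chrom <- ceiling(length(genes) / 5)
  rows <- map(seq_along(genes), function(i) {
    g <- genes[i]
    chrom <- paste0("chr", (i - 1) %/% per_chrom + 1)
    slot_start <- ((i - 1) %% per_chrom) * 4000L + 501L
    n_codons <- switch(g, FLT1 = 210L, VEGFB = 120L, ITGA2 = 200L,
                       sample(100:190, 1))
    cds_seq <- random_cds(n_codons, overrides[[g]])
    strand <- if (g %in% named) "+" else sample(c("+", "-"), 1)
    if (g == "ITGA2") {
      # two exons: 502 + 98 coding bases, 100 bp intron; the first intronic
      # base is the canonical donor G
      exs <- c(slot_start, slot_start + 602L)
      exe <- c(slot_start + 501L, slot_start + 699L)
    } else {
      exs <- slot_start
      exe <- slot_start + 3L * n_codons - 1L
    }
    tibble(gene = g, chrom = chrom, strand = strand,
           exon_start = list(exs), exon_end = list(exe),
           cds_start = min(exs), cds_end = max(exe),
           cds_seq = cds_seq)
  })
  validate_gene_models(bind_rows(rows))
}

# one planted variant row: variant columns + bookkeeping columns
plant_variant <- function(models, ped, gene, kind, cds_pos, alt,
                          carriers, carrier_gt = "0/1",
                          preds = list(), stage, family_id,
                          mq = 60, dp = 30, gq = 99,
                          dp_override = NULL, gq_override = NULL) {
  m <- as_model(models[models$gene == gene, ])
  if (kind == "sub") {
    pos <- cds_to_genomic(m, cds_pos)
    ref <- substr(m$cds_seq, cds_pos, cds_pos)
  } else if (kind == "splice_donor") {
    pos <- m$exon_end[1] + 1L          # first intronic base after exon 1
    ref <- "G"                          # canonical donor dinucleotide
  } else if (kind == "del") {
    pos <- cds_to_genomic(m, cds_pos)
    ref <- substr(m$cds_seq, cds_pos, cds_pos + nchar(alt))
    # alt passed as number of deleted bases for deletions
    d <- as.integer(alt)
    ref <- substr(m$cds_seq, cds_pos, cds_pos + d)
    alt <- substr(m$cds_seq, cds_pos, cds_pos)
  } else {
    abort(paste0("unknown planted-variant kind: ", kind))
  }
  ids <- ped$individual_id
  gt <- setNames(rep("0/0", length(ids)), ids)
  gt[carriers] <- carrier_gt
  dpv <- setNames(rep(as.integer(dp), length(ids)), ids)
  gqv <- setNames(rep(as.integer(gq), length(ids)), ids)
  for (id in names(dp_override)) dpv[id] <- as.integer(dp_override[[id]])
  for (id in names(gq_override)) gqv[id] <- as.integer(gq_override[[id]])
  tibble(
    chrom = m$chrom, pos = as.integer(pos), ref = ref, alt = as.character(alt),
    site_mq = mq,
    sift = preds$sift %||% NA_character_,
    polyphen2 = preds$polyphen2 %||% NA_character_,
    phylop = preds$phylop %||% NA_character_,
    mutation_taster = preds$mutation_taster %||% NA_character_,
    genotypes = list(tibble(sample_id = ids, gt = unname(gt),
                            dp = unname(dpv), gq = unname(gqv))),
    gene_planted = gene, stage = stage, family_id = family_id
  )
}

build_planted <- function(cfg, models, ped) {
  gs <- scenario_genes(cfg)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- plant_variant(models, ped, ...)
  if (cfg$plant_causal) {
    add("FLT1", "sub", 603L, "T", c("F1-MO", "F1-CH"),
        preds = list(sift = "tolerated", polyphen2 = "damaging",
                     phylop = "conserved", mutation_taster = "polymorphism"),
        stage = "final", family_id = "F1")
    add("VEGFB", "sub", 322L, "C", c("F4-II9", "F4-III7"),
        preds = list(sift = "tolerated", polyphen2 = "damaging",
                     phylop = "conserved", mutation_taster = "disease_causing"),
        stage = "final", family_id = "F4")
    add("ITGA2", "splice_donor", NA, "A",
        c("F4-I1", "F4-II3", "F4-III3", "F4-II8", "F4-III7", "F4-III8"),
        preds = list(mutation_taster = "disease_causing"),
        stage = "final", family_id = "F4")
  }
  if (cfg$plant_decoy_shared) {
    decoy_preds <- list(polyphen2 = "damaging", phylop = "conserved")
    add("KCNG4", "sub", 150L, "T", c("F1-MO", "F1-CH"),
        preds = decoy_preds, stage = "cross_family_decoy", family_id = "F1")
    add("KCNG4", "sub", 180L, "T", c("F4-II9", "F4-III7"),
        preds = decoy_preds, stage = "cross_family_decoy", family_id = "F4")
    add("NCOA6", "sub", 150L, "T", c("F1-MO", "F1-CH"),
        preds = decoy_preds, stage = "cross_family_decoy", family_id = "F1")
    add("NCOA6", "sub", 180L, "T", c("F4-II9", "F4-III7"),
        preds = decoy_preds, stage = "cross_family_decoy", family_id = "F4")
    add("KIAA1217", "sub", 150L, "T", c("F2-MO", "F2-CH", "F3-MO", "F3-CH"),
        preds = decoy_preds, stage = "cross_family_decoy", family_id = "F2+F3")
  }
  # filler overlap genes: one co-segregating missense per gene, distributed
  # across the four families; none in the focal set, some without consensus.
  # They exist to realize the configured candidate/DEG overlap, so they are
  # planted together with the causal variants.
  filler_genes <- if (cfg$plant_causal) gs$filler else character()
  fam_of <- rep(c("F1", "F2", "F3", "F4"), length.out = length(filler_genes))
  carrier_of <- list(F1 = c("F1-MO", "F1-CH"), F2 = c("F2-MO", "F2-CH"),
                     F3 = c("F3-MO", "F3-CH"), F4 = c("F4-II9", "F4-III7"))
  for (j in seq_along(filler_genes)) {
    g <- filler_genes[j]
    preds <- if (j %% 2 == 0) list(polyphen2 = "damaging", phylop = "conserved")
             else list(phylop = "conserved")
    if (j == 5 && length(filler_genes) >= 5) {
      # in-frame deletion of one codon (anchor at cds 150, delete 3 bases)
      rows[[length(rows) + 1]] <- plant_variant(
        models, ped, g, "del", 150L, 3L, carrier_of[[fam_of[j]]],
        preds = preds, stage = "filler", family_id = fam_of[j])
    } else if (j == 12 && length(filler_genes) >= 12) {
      # frameshift: single-base deletion
      rows[[length(rows) + 1]] <- plant_variant(
        models, ped, g, "del", 150L, 1L, carrier_of[[fam_of[j]]],
        preds = preds, stage = "filler", family_id = fam_of[j])
    } else {
      add(g, "sub", 150L, "T", carrier_of[[fam_of[j]]], preds = preds,
          stage = "filler", family_id = fam_of[j])
    }
  }
  if (cfg$plant_negative_decoys) {
    miss_preds <- list(polyphen2 = "damaging", phylop = "conserved")
    # shared only with the unaffected father: no affected pair
    add("DCY01", "sub", 150L, "T", c("F1-FA", "F1-CH"), preds = miss_preds,
        stage = "non_segregating", family_id = "F1")
    # homozygous parent: fails the strict heterozygous model
    r <- plant_variant(models, ped, "DCY02", "sub", 150L, "T",
                       c("F1-MO"), carrier_gt = "1/1", preds = miss_preds,
                       stage = "hom_parent", family_id = "F1")
    r$genotypes[[1]]$gt[r$genotypes[[1]]$sample_id == "F1-CH"] <- "0/1"
    rows[[length(rows) + 1]] <- r
    # co-segregating but present in the known-variant database
    add("DCY03", "sub", 150L, "T", c("F1-MO", "F1-CH"), preds = miss_preds,
        stage = "known_db", family_id = "F1")
    # quality failures: depth, site MQ, genotype quality
    add("DCY04", "sub", 150L, "T", c("F1-MO", "F1-CH"), preds = miss_preds,
        stage = "quality_depth", family_id = "F1",
        dp_override = list("F1-CH" = 4L))
    add("DCY05", "sub", 150L, "T", c("F1-MO", "F1-CH"), preds = miss_preds,
        stage = "quality_mq", family_id = "F1", mq = 20)
    add("DCY06", "sub", 150L, "T", c("F1-MO", "F1-CH"), preds = miss_preds,
        stage = "quality_gq", family_id = "F1",
        gq_override = list("F1-MO" = 20L))
    # dense cluster: three variants within 10 bp in DCY07's CDS
    for (cp in c(30L, 34L, 39L)) {
      m <- as_model(models[models$gene == "DCY07", ])
      refb <- substr(m$cds_seq, cp, cp)
      altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
      add("DCY07", "sub", cp, altb, c("F1-MO", "F1-CH"), preds = miss_preds,
          stage = "cluster", family_id = "F1")
    }
  }
  if (length(rows) == 0) return(NULL)
  bind_rows(rows)
}

# background variation: Mendelian-consistent genotypes over the pedigrees
build_background <- function(cfg, models, ped, taken) {
  n <- cfg$n_background_variants
  if (n == 0) return(NULL)
  span_start <- map_int(models$exon_start, min)
  span_end <- map_int(models$exon_end, max)
  per_chrom <- ceiling(nrow(models) / 5)
  chrom_len <- per_chrom * 4000L
  ids <- ped$individual_id
  founder <- is.na(ped$father_id) & is.na(ped$mother_id)
  taken_key <- paste(taken$chrom, taken$pos)
  positions <- list()
  rows <- vector("list", n)
  i <- 0L
  while (i < n) {
    in_cds <- runif(1) < 0.4
    if (in_cds) {
      mi <- sample(which(startsWith(models$gene, "BG")), 1)
      m <- as_model(models[mi, ])
      cp <- sample.int(nchar(m$cds_seq), 1)
      pos <- cds_to_genomic(m, cp)
      chrom <- m$chrom
      base <- substr(m$cds_seq, cp, cp)
      ref <- if (m$strand == "-") comp_base(base) else base
    } else {
      chrom <- paste0("chr", sample.int(5, 1))
      pos <- sample.int(chrom_len, 1)
      hit <- models$chrom == chrom & span_start - 20L <= pos &
        span_end + 20L >= pos
      if (any(hit)) next
      ref <- sample(c("A", "C", "G", "T"), 1)
    }
    # keep all sites at least 20 bp apart so only the deliberate cluster
    # triggers the cluster filter
    near <- positions[[chrom]]
    if (!is.null(near) && any(abs(near - pos) < 20L)) next
    if (paste(chrom, pos) %in% taken_key) next
    if (any(abs(taken$pos[taken$chrom == chrom] - pos) < 20L)) next
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    gt <- setNames(rep("0/0", length(ids)), ids)
    for (k in which(founder)) {
      gt[ids[k]] <- c("0/0", "0/1", "1/1")[
        stats::rbinom(1, 2, cfg$background_maf) + 1]
    }
    for (k in which(!founder)) {
      gt[ids[k]] <- mendelian_transmit(gt[[ped$father_id[k]]],
                                       gt[[ped$mother_id[k]]])
    }
    i <- i + 1L
    positions[[chrom]] <- c(positions[[chrom]], pos)
    rows[[i]] <- tibble(
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      site_mq = 60,
      sift = NA_character_, polyphen2 = NA_character_,
      phylop = NA_character_, mutation_taster = NA_character_,
      genotypes = list(tibble(
        sample_id = ids, gt = unname(gt),
        dp = as.integer(20 + stats::rbinom(length(ids), 20, 0.5)),
        gq = as.integer(60 + stats::rbinom(length(ids), 39, 0.5)))),
      in_cds = in_cds
    )
  }
  bind_rows(rows)
}

#' Generate an expression fixture with planted DE genes
#'
#' Emits a gene-by-sample log2 expression tibble for a two-group cohort in
#' which `n_deg` genes carry a case-group mean shift of
#' `deg_shift * within_group_sd` (random sign) and all other genes are null.
#'
#' @inheritParams scenario_config
#' @param genes Optional gene symbols (length `n_expression_genes`).
#' @param deg_gene_names Optional subset of `genes` to plant as DE; sampled
#'   when `NULL`.
#' @return List with `expr` (tibble), `groups` (tibble) and `deg_genes`.
#' @export
generate_expression_fixture <- function(seed = 7L,
                                        n_expression_genes = 20000L,
                                        n_deg = 1117L,
                                        deg_shift = 100,
                                        within_group_sd = 0.1,
                                        n_cases = 7L,
                                        n_controls = 5L,
                                        genes = NULL,
                                        deg_gene_names = NULL) {
  withr::with_seed(derive_seed(seed, "expression"), {
    genes <- genes %||% sprintf("G%05d", seq_len(n_expression_genes))
    stopifnot(length(genes) == n_expression_genes)
    deg_gene_names <- deg_gene_names %||% sample(genes, n_deg)
    stopifnot(all(deg_gene_names %in% genes), length(deg_gene_names) == n_deg)
    samples <- c(sprintf("CASE%02d", seq_len(n_cases)),
                 sprintf("CTRL%02d", seq_len(n_controls)))
    base <- stats::rnorm(n_expression_genes, 8, 2)
    mat <- matrix(stats::rnorm(n_expression_genes * length(samples),
                               0, within_group_sd),
                  nrow = n_expression_genes) + base
    shift <- deg_shift * within_group_sd *
      sample(c(-1, 1), n_deg, replace = TRUE)
    is_de <- match(deg_gene_names, genes)
    mat[is_de, seq_len(n_cases)] <- mat[is_de, seq_len(n_cases)] + shift
    expr <- as_tibble(as.data.frame(mat))
    names(expr) <- samples
    expr <- dplyr::bind_cols(tibble(gene = genes), expr)
    groups <- tibble(sample_id = samples,
                     group = rep(c("case", "control"), c(n_cases, n_controls)))
    list(expr = expr, groups = groups, deg_genes = deg_gene_names)
  })
}

build_serology <- function(cfg, ped) {
  withr::with_seed(derive_seed(cfg$seed, "serology"), {
    n <- nrow(ped)
    aff <- !is.na(ped$affected) & ped$affected
    tibble(
      subject_id = ped$individual_id,
      der_f = round(ifelse(aff, 4 + runif(n, 0, 12), runif(n, 0, 0.3)), 2),
      der_p = round(ifelse(aff, 1 + runif(n, 0, 6), runif(n, 0, 0.3)), 2),
      total_ige = round(ifelse(aff, 120 + runif(n, 0, 300),
                               20 + runif(n, 0, 60)), 1),
      asthma = 0L, eczema = 0L, other_allergic = 0L,
      chronic_disease = 0L, nasal_disease = 0L
    )
  })
}

#' Generate a complete synthetic input bundle with ground truth
#'
#' Emits, under `out_dir`: `variants.vcf` (merged multi-sample VCF),
#' `families.ped`, `gene_models.tsv`, `known_variants.tsv`,
#' `expression.tsv` + `groups.tsv`, `pathways.gmt`, `serology.tsv` and
#' `ground_truth.json`. Identical seeds give byte-identical bundles.
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory (created if needed).
#' @return List of class `famseg_scenario` with `paths` (named list),
#'   `truth` (ground-truth list) and `config`, invisibly returnable.
#' @export
generate_scenario <- function(config = scenario_config(), out_dir) {
  cfg <- config
  if (!inherits(cfg, "famseg_scenario_config")) {
    abort("config must come from scenario_config()")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ped <- paper_pedigree()
  gs <- scenario_genes(cfg)

  models <- withr::with_seed(derive_seed(cfg$seed, "models"),
                             build_models(cfg))
  planted <- build_planted(cfg, models, ped)
  bg <- withr::with_seed(
    derive_seed(cfg$seed, "background"),
    build_background(cfg, models, ped,
                     taken = planted %||% tibble(chrom = character(),
                                                 pos = integer()))
  )

  # known-variant set: all coding background, a fraction of the rest, plus
  # the planted known-database decoy
  known_rows <- list()
  if (!is.null(bg)) {
    keep_known <- withr::with_seed(
      derive_seed(cfg$seed, "known"),
      bg$in_cds | runif(nrow(bg)) < cfg$known_db_coverage
    )
    known_rows[[1]] <- bg[keep_known, c("chrom", "pos", "ref", "alt")]
  }
  if (!is.null(planted) && any(planted$stage == "known_db")) {
    known_rows[[2]] <- planted[planted$stage == "known_db",
                               c("chrom", "pos", "ref", "alt")]
  }
  known <- if (length(known_rows) > 0) bind_rows(known_rows)
  else tibble(chrom = character(), pos = integer(),
              ref = character(), alt = character())

  variants <- bind_rows(
    if (!is.null(planted)) select(planted, dplyr::all_of(variant_cols)),
    if (!is.null(bg)) select(bg, dplyr::all_of(variant_cols))
  )
  if (is.null(variants) || nrow(variants) == 0) variants <- empty_variants()
  variants <- arrange(variants, .data$chrom, .data$pos, .data$alt)

  # gene sets: focal-adhesion-like set with the causal genes, decoy sets of
  # background genes
  bg_genes <- models$gene[startsWith(models$gene, "BG")]
  sets <- withr::with_seed(derive_seed(cfg$seed, "sets"), {
    s <- list(FOCAL_ADHESION = c(gs$causal, gs$focal_extra))
    pool <- bg_genes
    for (j in seq_len(cfg$n_decoy_sets)) {
      pick <- sample(pool, cfg$decoy_set_size)
      pool <- setdiff(pool, pick)
      s[[paste0("PATHWAY_", LETTERS[j])]] <- sort(pick)
    }
    s
  })

  # expression: model genes plus filler genes; the DE list contains exactly
  # the overlap genes (causal + filler candidates) and otherwise only
  # non-candidate filler genes
  overlap_genes <- c(gs$causal, gs$filler)
  expr_only <- sprintf("EXPR%05d", seq_len(cfg$n_expression_genes -
                                             nrow(models)))
  expr_genes <- c(models$gene, expr_only)
  deg_named <- withr::with_seed(
    derive_seed(cfg$seed, "degpick"),
    c(overlap_genes, sample(expr_only, cfg$n_deg - length(overlap_genes)))
  )
  fx <- generate_expression_fixture(
    seed = derive_seed(cfg$seed, "exprvals"),
    n_expression_genes = cfg$n_expression_genes, n_deg = cfg$n_deg,
    deg_shift = cfg$deg_shift, within_group_sd = cfg$within_group_sd,
    n_cases = cfg$n_cases, n_controls = cfg$n_controls,
    genes = expr_genes, deg_gene_names = deg_named
  )

  serology <- build_serology(cfg, ped)

  # ground truth from generator bookkeeping
  truth <- scenario_truth(cfg, ped, planted, variants, deg_named,
                          overlap_genes)

  paths <- list(
    vcf = file.path(out_dir, "variants.vcf"),
    ped = file.path(out_dir, "families.ped"),
    gene_models = file.path(out_dir, "gene_models.tsv"),
    known = file.path(out_dir, "known_variants.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    groups = file.path(out_dir, "groups.tsv"),
    gmt = file.path(out_dir, "pathways.gmt"),
    serology = file.path(out_dir, "serology.tsv"),
    truth = file.path(out_dir, "ground_truth.json")
  )
  write_vcf(variants, paths$vcf, samples = ped$individual_id)
  write_ped(ped, paths$ped)
  write_gene_models(models, paths$gene_models)
  write_known_set(known, paths$known)
  write_expression(fx$expr, paths$expression)
  write_groups(fx$groups, paths$groups)
  write_gmt(sets, paths$gmt)
  write_serology(serology, paths$serology)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  structure(list(paths = paths, truth = truth, config = cfg),
            class = "famseg_scenario")
}

scenario_truth <- function(cfg, ped, planted, variants, deg_named,
                           overlap_genes) {
  gs <- scenario_genes(cfg)
  key <- function(df) variant_key(df$chrom, df$pos, df$ref, df$alt)
  if (!is.null(planted) && nrow(planted) > 0) {
    removed_stages <- c("known_db", "quality_depth", "quality_mq",
                        "quality_gq", "cluster")
    surviving <- planted[!planted$stage %in% removed_stages, ]
    pair_ok <- planted[planted$stage %in%
                         c("final", "cross_family_decoy", "filler"), ]
    nssi <- setNames(
      map_int(ped$individual_id, function(id) {
        sum(map_lgl(surviving$genotypes,
                    function(g) g$gt[g$sample_id == id] %in% c("0/1", "1/1")))
      }),
      ped$individual_id)
    # a variant may co-segregate in several families (family_id "F2+F3")
    fam_expand <- tibble(
      family_id = unlist(strsplit(pair_ok$family_id, "+", fixed = TRUE)),
      key = rep(key(pair_ok),
                lengths(strsplit(pair_ok$family_id, "+", fixed = TRUE)))
    )
    pair_shared <- map(split(fam_expand$key, fam_expand$family_id), sort)
    truth_final <- key(planted[planted$stage == "final", ])
  } else {
    nssi <- setNames(rep(0L, nrow(ped)), ped$individual_id)
    pair_shared <- list()
    truth_final <- character()
  }
  list(
    seed = cfg$seed,
    per_individual_nssi = as.list(nssi),
    pair_shared_keys = pair_shared,
    cross_family_genes = if (cfg$plant_decoy_shared) sort(gs$decoy_shared)
                         else character(),
    intersection_genes = if (cfg$plant_causal) sort(overlap_genes)
                         else character(),
    deg_genes = sort(deg_named),
    final_variants = sort(truth_final),
    compound_het_carriers = if (cfg$plant_causal) "F4-III7" else character(),
    n_variants_emitted = nrow(variants)
  )
}
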