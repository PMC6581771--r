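# fixtures built in code: tidy variant rows, toy transcript models, tiny
# VCF/PED files written to tempdir

mk_variant <- function(pos, chrom = "chr1", ref = "A", alt = "T", mq = 60,
                       gts = c(S1 = "0/1"), dp = 30, gq = 99,
                       sift = NA, polyphen2 = NA, phylop = NA,
                       mutation_taster = NA) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    site_mq = as.numeric(mq),
    sift = as.character(sift), polyphen2 = as.character(polyphen2),
    phylop = as.character(phylop),
    mutation_taster = as.character(mutation_taster),
    genotypes = list(tibble::tibble(
      sample_id = names(gts), gt = unname(gts),
      dp = as.integer(rep_len(dp, length(gts))),
      gq = as.integer(rep_len(gq, length(gts)))
    ))
  )
}

mk_variants <- function(pos, ...) {
  dplyr::bind_rows(lapply(pos, function(p) mk_variant(p, ...)))
}

# toy transcript model from explicit codons; optional intron after a given
# number of CDS bases (exon boundary), optional minus strand
toy_model <- function(codons, gene = "TOY", chrom = "chr1", strand = "+",
                      start = 1001L, intron_after = NULL, intron_len = 100L) {
  cds_seq <- paste(codons, collapse = "")
  len <- nchar(cds_seq)
  if (is.null(intron_after)) {
    exs <- start
    exe <- start + len - 1L
  } else {
    exs <- c(start, start + intron_after + intron_len)
    exe <- c(start + intron_after - 1L,
             start + intron_after + intron_len + (len - intron_after) - 1L)
  }
  tibble::tibble(gene = gene, chrom = chrom, strand = strand,
                 exon_start = list(as.integer(exs)),
                 exon_end = list(as.integer(exe)),
                 cds_start = min(exs), cds_end = max(exe), cds_seq = cds_seq)
}

random_codons <- function(n) {
  pool <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  sample(pool, n, replace = TRUE)
}

trio_ped <- function(fam = "F1", mother_affected = TRUE,
                     father_affected = FALSE, child_affected = TRUE) {
  tibble::tibble(
    family_id = fam,
    individual_id = paste0(fam, c("-FA", "-MO", "-CH")),
    father_id = c(NA, NA, paste0(fam, "-FA")),
    mother_id = c(NA, NA, paste0(fam, "-MO")),
    sex = c(1L, 2L, 1L),
    affected = c(father_affected, mother_affected, child_affected)
  )
}

write_mini_vcf <- function(lines, samples = c("S1", "S2")) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    lines
  ), f)
  f
}

# small scenario configuration for fast generator tests
small_config <- function(seed = 11L, ...) {
  defaults <- list(seed = seed, n_background_variants = 60L,
                   n_gene_models = 200L, n_expression_genes = 2500L,
                   n_deg = 100L, candidate_deg_overlap = 10L,
                   n_decoy_sets = 2L, decoy_set_size = 20L)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(famseg::scenario_config, defaults)
}
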