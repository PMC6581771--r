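# VCF reading/writing. Parsing is delegated to vcfR; this layer adds strict
# structural validation with line numbers, multi-allelic splitting with
# genotype-index remapping, and the tidy variant representation used by the
# rest of the pipeline.

empty_variants <- function() {
  tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    site_mq = double(), sift = character(), polyphen2 = character(),
    phylop = character(), mutation_taster = character(), genotypes = list()
  )
}

# normalize one diploid GT string relative to the alt allele index kept after
# splitting: "0/1" vs alt 1 -> "0/1"; "1/2" vs alt 1 -> "other"; phase ignored
normalize_gt <- function(gt, alt_index) {
  if (is.na(gt) || gt == "." || gt == "./." || gt == ".|.") return("./.")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) == 1) alleles <- rep(alleles, 2)
  code <- vapply(alleles, function(a) {
    if (a == ".") "m" else if (a == "0") "r"
    else if (a == as.character(alt_index)) "a" else "o"
  }, character(1))
  code <- paste(sort(code), collapse = "")
  switch(code,
         "mm" = "./.", "rr" = "0/0", "ar" = "0/1", "aa" = "1/1",
         "other")
}

#' Read a multi-sample VCF into a tidy variant table
#'
#' Parses a VCF v4.x file, splits multi-allelic records so every row carries
#' exactly one alternate allele (genotype allele indices are remapped per
#' split; alleles belonging to another alternate are classed `"other"`), and
#' attaches per-sample genotype calls. Genotype phase is ignored. Site
#' mapping quality is taken from the `MQ` INFO key and functional-predictor
#' calls from the `SIFT`, `POLYPHEN2`, `PHYLOP` and `MTASTER` INFO keys; all
#' are `NA` when absent (absent quality values fail the corresponding quality
#' filter downstream).
#'
#' @param path Path to a VCF file.
#' @return A tibble sorted by (chrom, pos, alt) with columns `chrom`, `pos`,
#'   `ref`, `alt`, `site_mq`, the four predictor-call columns, and a
#'   `genotypes` list-column of per-sample tibbles (`sample_id`, `gt`, `dp`,
#'   `gq`).
#' @examples
#' f <- tempfile(fileext = ".vcf")
#' writeLines(c("##fileformat=VCFv4.2",
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
#'   "chr1\t100\t.\tA\tT\t.\t.\tMQ=60\tGT:DP:GQ\t0/1:20:99"), f)
#' read_vcf(f)
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  lines <- readLines(path)
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_i) != 1) {
    abort("malformed VCF header: expected exactly one #CHROM line")
  }
  meta <- lines[seq_len(hdr_i - 1)]
  if (!all(startsWith(meta, "##"))) {
    bad <- which(!startsWith(meta, "##"))[1]
    abort(sprintf("malformed VCF header at line %d: expected '##' meta line", bad))
  }
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  ncol_expect <- length(hdr)
  if (ncol_expect < 8) abort("malformed VCF header: fewer than 8 columns")
  has_samples <- ncol_expect > 9
  if (ncol_expect == 9) abort("malformed VCF header: FORMAT column without samples")
  body_i <- seq.int(hdr_i + 1, length.out = length(lines) - hdr_i)
  for (i in body_i) {
    if (!nzchar(lines[i])) next
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != ncol_expect) {
      abort(sprintf("ragged VCF row at line %d: %d fields, expected %d",
                    i, nf, ncol_expect))
    }
    if (has_samples) {
      fmt <- strsplit(lines[i], "\t", fixed = TRUE)[[1]][9]
      if (!("GT" %in% strsplit(fmt, ":", fixed = TRUE)[[1]])) {
        abort(sprintf("VCF format error at line %d: FORMAT lacks GT", i))
      }
    }
  }

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) return(empty_variants())

  info_key <- function(key) {
    val <- vcfR::extract.info(vcf, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else as.character(val)
  }
  mq <- suppressWarnings(as.numeric(info_key("MQ")))
  preds <- list(sift = info_key("SIFT"), polyphen2 = info_key("POLYPHEN2"),
                phylop = info_key("PHYLOP"), mutation_taster = info_key("MTASTER"))

  samples <- if (has_samples) colnames(vcf@gt)[-1] else character()
  if (has_samples) {
    gt_m <- vcfR::extract.gt(vcf, element = "GT")
    dp_m <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    gq_m <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  }

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    sub <- vector("list", length(alts))
    for (a in seq_along(alts)) {
      geno <- if (has_samples) {
        tibble(
          sample_id = samples,
          gt = vapply(gt_m[i, , drop = TRUE], normalize_gt, character(1),
                      alt_index = a, USE.NAMES = FALSE),
          dp = as.integer(round(dp_m[i, , drop = TRUE])),
          gq = as.integer(round(gq_m[i, , drop = TRUE]))
        )
      } else {
        tibble(sample_id = character(), gt = character(),
               dp = integer(), gq = integer())
      }
      sub[[a]] <- tibble(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[a], site_mq = mq[i],
        sift = preds$sift[i], polyphen2 = preds$polyphen2[i],
        phylop = preds$phylop[i], mutation_taster = preds$mutation_taster[i],
        genotypes = list(geno)
      )
    }
    rows[[i]] <- bind_rows(sub)
  }
  out <- bind_rows(rows)
  validate_variants(out)
  arrange(out, .data$chrom, .data$pos, .data$alt)
}

validate_variants <- function(variants) {
  assert_variants(variants)
  if (any(variants$pos < 1)) abort("variant positions must be >= 1")
  ok_seq <- grepl("^[ACGT]+$", variants$ref) & grepl("^[ACGT]+$", variants$alt)
  if (!all(ok_seq)) {
    abort(sprintf("ref/alt alleles must be nonempty A/C/G/T strings (offending key: %s)",
                  variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)[!ok_seq][1]))
  }
  if (any(variants$ref == variants$alt)) abort("ref and alt alleles must differ")
  dup <- map_lgl(variants$genotypes, function(g) anyDuplicated(g$sample_id) > 0)
  if (any(dup)) abort("duplicate sample ids within a variant's genotype table")
  invisible(variants)
}

#' Write a tidy variant table as VCF v4.2
#'
#' Inverse of [read_vcf()] for already-split (biallelic) variant tables.
#' Genotypes classed `"other"` (alleles of a different alternate at the same
#' site) cannot be reconstructed and are written as missing, with a warning.
#'
#' @param variants Variant tibble as returned by [read_vcf()].
#' @param path Output file path.
#' @param samples Sample column order; defaults to the order in the first
#'   genotype table.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, samples = NULL) {
  assert_variants(variants)
  variants <- arrange(variants, .data$chrom, .data$pos, .data$alt)
  samples <- samples %||%
    (if (nrow(variants) > 0) variants$genotypes[[1]]$sample_id else character())
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=SIFT,Number=1,Type=String,Description=\"SIFT call\">",
    "##INFO=<ID=POLYPHEN2,Number=1,Type=String,Description=\"PolyPhen2 call\">",
    "##INFO=<ID=PHYLOP,Number=1,Type=String,Description=\"PhyloP call\">",
    "##INFO=<ID=MTASTER,Number=1,Type=String,Description=\"MutationTaster call\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  fmt1 <- function(x) ifelse(is.na(x), ".", as.character(x))
  body <- map_chr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    info <- c(
      if (!is.na(v$site_mq)) paste0("MQ=", fmt1(v$site_mq)),
      if (!is.na(v$sift)) paste0("SIFT=", v$sift),
      if (!is.na(v$polyphen2)) paste0("POLYPHEN2=", v$polyphen2),
      if (!is.na(v$phylop)) paste0("PHYLOP=", v$phylop),
      if (!is.na(v$mutation_taster)) paste0("MTASTER=", v$mutation_taster)
    )
    info <- if (length(info) == 0) "." else paste(info, collapse = ";")
    g <- v$genotypes[[1]]
    g <- g[match(samples, g$sample_id), ]
    gt <- g$gt
    if (any(gt == "other", na.rm = TRUE)) {
      warn("genotypes classed 'other' written as missing ('./.')")
      gt[gt == "other"] <- "./."
    }
    gt[is.na(gt)] <- "./."
    calls <- paste(gt, fmt1(g$dp), fmt1(g$gq), sep = ":")
    paste(c(v$chrom, v$pos, ".", v$ref, v$alt, ".", ".", info,
            "GT:DP:GQ", calls), collapse = "\t")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}
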