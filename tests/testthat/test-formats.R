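test_that("read_vcf parses multi-sample records with quality fields", {
  f <- write_mini_vcf(
    "chr13\t29008268\t.\tA\tT\t.\t.\tMQ=60\tGT:DP:GQ\t0/1:20:99\t0/1:18:95")
  v <- read_vcf(f)
  expect_equal(nrow(v), 1)
  expect_equal(v$pos, 29008268L)
  expect_equal(v$site_mq, 60)
  g <- v$genotypes[[1]]
  expect_equal(g$gt, c("0/1", "0/1"))
  expect_equal(g$dp, c(20L, 18L))
  expect_equal(g$gq, c(99L, 95L))
})

test_that("read_vcf returns an empty table for a body-less file", {
  f <- write_mini_vcf(character())
  v <- read_vcf(f)
  expect_equal(nrow(v), 0)
  expect_true(all(c("chrom", "pos", "ref", "alt", "genotypes") %in% names(v)))
})

test_that("multi-allelic records split with remapped genotype indices", {
  f <- write_mini_vcf(
    "chr1\t500\t.\tA\tT,C\t.\t.\tMQ=55\tGT:DP:GQ\t1/2:30:90\t0/1:25:80\t2/2:22:70",
    samples = c("S1", "S2", "S3"))
  v <- read_vcf(f)
  expect_equal(nrow(v), 2)            # splitting conserves (site, alt) pairs
  expect_equal(v$alt, c("C", "T"))    # sorted by (chrom, pos, alt)
  # hand-expanded oracle for every sample x split:
  vt <- v[v$alt == "T", ]$genotypes[[1]]
  expect_equal(vt$gt, c("other", "0/1", "other"))
  vc <- v[v$alt == "C", ]$genotypes[[1]]
  expect_equal(vc$gt, c("other", "other", "1/1"))
  expect_true(all(v$site_mq == 55))
})

test_that("read_vcf output is totally ordered by (chrom, pos, alt)", {
  f <- write_mini_vcf(c(
    "chr2\t100\t.\tG\tA\t.\t.\tMQ=60\tGT:DP:GQ\t0/1:30:99\t0/0:30:99",
    "chr1\t300\t.\tC\tT\t.\t.\tMQ=60\tGT:DP:GQ\t0/1:30:99\t0/0:30:99",
    "chr1\t100\t.\tA\tG,T\t.\t.\tMQ=60\tGT:DP:GQ\t0/1:30:99\t0/0:30:99"))
  v <- read_vcf(f)
  key <- paste(v$chrom, sprintf("%09d", v$pos), v$alt)
  expect_equal(key, sort(key))
})

test_that("malformed VCF bodies raise line-numbered errors", {
  f <- write_mini_vcf(
    "chr1\t100\t.\tA\tT\t.\t.\tMQ=60\tGT:DP:GQ\t0/1:20:99\t0/0:25:90")
  lines <- readLines(f)
  ragged <- tempfile(fileext = ".vcf")
  writeLines(c(lines, "chr1\t200\t.\tA"), ragged)
  expect_error(read_vcf(ragged), "ragged.*line 8")
  nogt <- tempfile(fileext = ".vcf")
  body <- "chr1\t100\t.\tA\tT\t.\t.\tMQ=60\tDP:GQ\t20:99\t18:95"
  writeLines(c(lines[1:6], body), nogt)
  expect_error(read_vcf(nogt), "FORMAT lacks GT")
  noheader <- tempfile(fileext = ".vcf")
  writeLines(lines[-6], noheader)
  expect_error(read_vcf(noheader), "header")
})

test_that("VCF round-trip preserves every field", {
  v <- dplyr::bind_rows(
    mk_variant(100, ref = "A", alt = "T", gts = c(S1 = "0/1", S2 = "0/0"),
               sift = "tolerated", polyphen2 = "damaging"),
    mk_variant(250, ref = "AT", alt = "A", gts = c(S1 = "1/1", S2 = "./."),
               mq = 42.5)
  )
  f <- tempfile(fileext = ".vcf")
  write_vcf(v, f)
  v2 <- read_vcf(f)
  expect_equal(as.data.frame(v2), as.data.frame(v))
})

test_that("read_ped encodes affection and unknown parents; pairs detected", {
  f <- tempfile(fileext = ".ped")
  writeLines(c("F1 MO 0 0 2 2", "F1 FA 0 0 1 0", "F1 CH FA MO 1 2"), f)
  ped <- read_ped(f)
  expect_equal(nrow(ped), 3)
  expect_true(is.na(ped$affected[ped$individual_id == "FA"]))
  pairs <- affected_pairs(ped, "F1")
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$parent_id, "MO")
  expect_equal(pairs$child_id, "CH")
})

test_that("an empty PED file yields an empty pedigree", {
  f <- tempfile(fileext = ".ped")
  writeLines(character(), f)
  expect_equal(nrow(read_ped(f)), 0)
})

test_that("a 12-member extended family parses with 6 affected members", {
  # two sibships; affected: II3, III3, II8, II9, III7, III8
  f <- tempfile(fileext = ".ped")
  writeLines(c(
    "F4 I1 0 0 1 1",   "F4 I2 0 0 2 1",
    "F4 II3 I1 I2 1 2", "F4 II4 0 0 2 1", "F4 II5 I1 I2 1 1",
    "F4 II8 I1 I2 1 2", "F4 II9 0 0 2 2",
    "F4 III3 II3 II4 1 2", "F4 III4 II3 II4 2 1",
    "F4 III7 II8 II9 2 2", "F4 III8 II8 II9 1 2", "F4 III9 II8 II9 2 1"), f)
  ped <- read_ped(f)
  expect_equal(nrow(ped), 12)
  expect_equal(sum(ped$affected, na.rm = TRUE), 6)
  expect_gte(nrow(affected_pairs(ped, "F4")), 3)
})

test_that("dangling parent ids are a validation error naming the id", {
  f <- tempfile(fileext = ".ped")
  writeLines(c("F1 CH GHOST 0 1 2"), f)
  expect_error(read_ped(f), "dangling.*GHOST")
})

test_that("GMT parsing returns named sets of unique genes", {
  f <- tempfile(fileext = ".gmt")
  writeLines("FOCAL_ADHESION\tna\tITGA2\tFLT1\tVEGFB", f)
  sets <- read_gmt(f)
  expect_equal(names(sets), "FOCAL_ADHESION")
  expect_length(sets$FOCAL_ADHESION, 3)
  f2 <- tempfile(fileext = ".gmt")
  write_gmt(sets, f2)
  expect_equal(read_gmt(f2), sets)
})

test_that("gene-model validation enforces the CDS frame invariant", {
  good <- tibble::tibble(gene = "G1", chrom = "chr1", strand = "+",
                         exon_start = list(c(101L, 301L)),
                         exon_end = list(c(200L, 401L)),
                         cds_start = 101L, cds_end = 401L,
                         cds_seq = paste(rep("A", 201), collapse = ""))
  expect_silent(validate_gene_models(good))
  bad <- good
  bad$exon_end <- list(c(200L, 400L))  # CDS length 200: not a codon multiple
  bad$cds_end <- 400L
  bad$cds_seq <- paste(rep("A", 200), collapse = "")
  expect_error(validate_gene_models(bad), "G1.*multiple of 3")
})

test_that("gene models, expression, groups, known set and serology round-trip", {
  withr::with_seed(5, {
    models <- dplyr::bind_rows(
      toy_model(random_codons(60), gene = "GA"),
      toy_model(random_codons(80), gene = "GB", strand = "-", start = 5001L,
                intron_after = 90L)
    )
  })
  f <- tempfile(fileext = ".tsv")
  write_gene_models(models, f)
  expect_equal(as.data.frame(read_gene_models(f)), as.data.frame(models))

  expr <- tibble::tibble(gene = c("GA", "GB"), S1 = c(1.5, 2.5),
                         S2 = c(0.1, -3))
  fe <- tempfile(fileext = ".tsv")
  write_expression(expr, fe)
  expect_equal(as.data.frame(read_expression(fe)), as.data.frame(expr))

  groups <- tibble::tibble(sample_id = c("S1", "S2"),
                           group = c("case", "control"))
  fg <- tempfile(fileext = ".tsv")
  write_groups(groups, fg)
  expect_equal(as.data.frame(read_groups(fg)), as.data.frame(groups))

  known <- tibble::tibble(chrom = "chr1", pos = c(5L, 9L), ref = "A",
                          alt = c("T", "G"))
  fk <- tempfile(fileext = ".tsv")
  write_known_set(known, fk)
  expect_equal(as.data.frame(read_known_set(fk)), as.data.frame(known))

  ser <- tibble::tibble(subject_id = "P1", der_f = 4, der_p = 2,
                        total_ige = 150, asthma = 0L, eczema = 0L,
                        other_allergic = 0L, chronic_disease = 0L,
                        nasal_disease = 0L)
  fs <- tempfile(fileext = ".tsv")
  write_serology(ser, fs)
  expect_equal(as.data.frame(read_serology(fs)), as.data.frame(ser))
})

test_that("duplicate expression genes are rejected", {
  f <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene = c("GA", "GA"), S1 = c(1, 2)), f)
  expect_error(read_expression(f), "duplicate gene")
})
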