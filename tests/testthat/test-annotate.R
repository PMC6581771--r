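test_that("residue_index implements codon arithmetic", {
  expect_equal(residue_index(603), 201L)
  expect_equal(residue_index(1), 1L)
  expect_equal(residue_index(322), 108L)
  # non-decreasing, exactly 3 consecutive positions per residue
  idx <- residue_index(1:300)
  expect_true(all(diff(idx) >= 0))
  expect_true(all(table(idx) == 3))
  expect_error(residue_index(0), ">= 1")
})

test_that("genomic positions map to CDS coordinates on the plus strand", {
  m <- toy_model(rep("GAA", 210), start = 1001L)
  expect_equal(genomic_to_cds(m, 1603L)$cds_pos, 603L)
  expect_equal(genomic_to_cds(m, 1001L)$cds_pos, 1L)
  expect_null(genomic_to_cds(m, 5000L))
})

test_that("the first intronic base after an exon renders as '+1'", {
  # first exon carries 502 coding bases
  m <- toy_model(rep("GAA", 200), intron_after = 502L)
  pos <- m$exon_end[[1]][1] + 1L
  coord <- genomic_to_cds(m, pos)
  expect_equal(coord$cds_pos, 502L)
  expect_equal(coord$intron_offset, 1L)
  expect_equal(render_cds_coord(coord), "502+1")
  # deep intron positions anchor to the nearer boundary
  acceptor_side <- m$exon_start[[1]][2] - 1L
  coord2 <- genomic_to_cds(m, acceptor_side)
  expect_equal(coord2$intron_offset, -1L)
  expect_equal(coord2$cds_pos, 503L)
})

test_that("minus-strand mapping agrees with the mirrored plus-strand model", {
  withr::with_seed(401, {
    for (rep in 1:10) {
      n_cod <- sample(40:80, 1)
      codons <- random_codons(n_cod)
      intron_after <- sample(seq(30, 3 * n_cod - 30, by = 1), 1)
      minus <- toy_model(codons, strand = "-", start = 2001L,
                         intron_after = intron_after)
      # mirrored construction: flip coordinates around a pivot so the
      # transcript reads left-to-right, same cds_seq on the plus strand
      pivot <- 10000L
      exs <- sort(pivot - minus$exon_end[[1]])
      exe <- sort(pivot - minus$exon_start[[1]])
      plus <- tibble::tibble(gene = "TOY", chrom = "chr1", strand = "+",
                             exon_start = list(exs), exon_end = list(exe),
                             cds_start = min(exs), cds_end = max(exe),
                             cds_seq = minus$cds_seq)
      span <- seq(min(minus$exon_start[[1]]), max(minus$exon_end[[1]]))
      for (pos in sample(span, 25)) {
        a <- genomic_to_cds(minus, pos)
        b <- genomic_to_cds(plus, pivot - pos)
        expect_identical(a, b)
      }
    }
  })
})

test_that("cds_to_genomic inverts genomic_to_cds on coding positions", {
  withr::with_seed(402, {
    for (rep in 1:10) {
      n_cod <- sample(30:70, 1)
      strand <- sample(c("+", "-"), 1)
      intron_after <- if (rep %% 2 == 0) sample(seq(9, 3 * n_cod - 9), 1)
      else NULL
      m <- toy_model(random_codons(n_cod), strand = strand,
                     intron_after = intron_after)
      for (cp in sample.int(3 * n_cod, 20)) {
        g <- cds_to_genomic(m, cp)
        expect_equal(genomic_to_cds(m, g)$cds_pos, cp)
      }
    }
  })
})

test_that("the worked-example substitutions annotate exactly", {
  # E201D: codon 201 GAA, third base A>T
  m1 <- toy_model(rep("GAA", 210))
  v1 <- list(pos = cds_to_genomic(m1, 603L), ref = "A", alt = "T")
  c1 <- annotate_substitution(m1, v1)
  expect_equal(c1$category, "nonsynonymous")
  expect_equal(c1$hgvs_c, "c.603A>T")
  expect_equal(c1$hgvs_p, "p.E201D")
  expect_equal(c1$residue_index, 201L)
  # synonymous third-base change in the same codon
  v1s <- list(pos = v1$pos, ref = "A", alt = "G")
  expect_equal(annotate_substitution(m1, v1s)$category, "synonymous")
  # S108R: codon 108 AGC, first base A>C
  m2 <- toy_model(rep("AGC", 120))
  v2 <- list(pos = cds_to_genomic(m2, 322L), ref = "A", alt = "C")
  c2 <- annotate_substitution(m2, v2)
  expect_equal(c2$category, "nonsynonymous")
  expect_equal(c2$hgvs_p, "p.S108R")
  expect_equal(c2$residue_index, 108L)
  # three-letter rendering available
  expect_equal(annotate_substitution(m2, v2, hgvs_p_style = "three")$hgvs_p,
               "p.Ser108Arg")
})

test_that("a reference allele disagreeing with the model is an error", {
  m <- toy_model(rep("GAA", 50))
  v <- list(pos = cds_to_genomic(m, 30L), ref = "C", alt = "T")
  expect_error(annotate_substitution(m, v), "reference mismatch")
})

test_that("substitution categories match a full-CDS translation oracle", {
  withr::with_seed(403, {
    for (rep in 1:6) {
      strand <- sample(c("+", "-"), 1)
      codons <- random_codons(sample(30:60, 1))
      m <- toy_model(codons, strand = strand,
                     intron_after = sample(seq(9, 3 * length(codons) - 9), 1))
      len <- 3 * length(codons)
      for (i in 1:40) {
        cp <- sample.int(len, 1)
        ref_c <- substr(m$cds_seq, cp, cp)
        alt_c <- sample(setdiff(c("A", "C", "G", "T"), ref_c), 1)
        flip <- function(b) if (strand == "-") chartr("ACGT", "TGCA", b) else b
        v <- list(pos = cds_to_genomic(m, cp), ref = flip(ref_c),
                  alt = flip(alt_c))
        got <- annotate_substitution(m, v)
        p_ref <- translate_oracle(m$cds_seq)
        p_alt <- translate_oracle(mutate_cds(m$cds_seq, cp, alt_c))
        idx <- got$residue_index
        expected <- if (p_ref == p_alt) "synonymous"
        else if (substr(p_alt, idx, idx) == "*") "stop_gained"
        else if (substr(p_ref, idx, idx) == "*") "stop_lost"
        else "nonsynonymous"
        expect_equal(got$category, expected)
        # the changed residue is the reported one
        if (expected != "synonymous") {
          diffs <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
          expect_equal(diffs, idx)
        }
      }
    }
  })
})

test_that("canonical splice dinucleotides classify as donor/acceptor", {
  m <- toy_model(rep("GAA", 200), intron_after = 502L)
  donor_pos <- m$exon_end[[1]][1] + 1L
  sp <- classify_splice(m, list(pos = donor_pos, ref = "G", alt = "A"))
  expect_equal(sp$category, "splice_donor")
  expect_equal(sp$hgvs_c, "c.502+1G>A")
  acc <- classify_splice(m, list(pos = m$exon_start[[1]][2] - 1L,
                                 ref = "G", alt = "C"))
  expect_equal(acc$category, "splice_acceptor")
  # boundary sweep: only offsets +/-1 and +/-2 are splice sites
  for (k in 1:10) {
    d <- classify_splice(m, list(pos = donor_pos + k - 1L, ref = "G",
                                 alt = "A"))
    expect_equal(d$category, if (k <= 2) "splice_donor" else "intronic")
    a <- classify_splice(m, list(pos = m$exon_start[[1]][2] - k, ref = "G",
                                 alt = "C"))
    expect_equal(a$category, if (k <= 2) "splice_acceptor" else "intronic")
  }
})

test_that("indel frame classification follows length difference mod 3", {
  m <- toy_model(rep("GAA", 100))
  pos <- cds_to_genomic(m, 30L)
  del1 <- annotate_indel(m, list(pos = pos, ref = "AG", alt = "A"))
  expect_equal(del1$category, "frameshift_indel")
  del3 <- annotate_indel(m, list(pos = pos, ref = "AGAA", alt = "A"))
  expect_equal(del3$category, "inframe_indel")
  expect_match(del3$hgvs_c, "^c\\.31_33del$")
  withr::with_seed(404, {
    for (i in 1:50) {
      ins_len <- sample(1:9, 1)
      is_ins <- runif(1) < 0.5
      ref <- if (is_ins) "A" else paste(rep("A", ins_len + 1), collapse = "")
      alt <- if (is_ins) paste(rep("A", ins_len + 1), collapse = "") else "A"
      got <- annotate_indel(m, list(pos = pos, ref = ref, alt = alt))
      expect_equal(got$category,
                   if (ins_len %% 3 == 0) "inframe_indel" else "frameshift_indel")
    }
  })
})

test_that("NS/SS/I membership covers exactly the retained classes", {
  expect_true(all(is_nssi(c("nonsynonymous", "stop_gained", "stop_lost",
                            "splice_donor", "splice_acceptor",
                            "frameshift_indel", "inframe_indel"))))
  expect_false(any(is_nssi(c("synonymous", "intronic", "intergenic"))))
})

test_that("predictor consensus counts deleterious votes", {
  v <- mk_variant(100, sift = "tolerated", polyphen2 = "damaging",
                  phylop = "conserved", mutation_taster = "disease_causing")
  expect_true(predictor_consensus(v, 2))
  expect_true(predictor_consensus(v, 3))
  expect_false(predictor_consensus(v, 4))
  none <- mk_variant(100)
  expect_false(predictor_consensus(none, 1))
  expect_false(predictor_consensus(v, 5))  # more votes than predictors
})

test_that("annotate_variants routes variants to the right consequence call", {
  models <- dplyr::bind_rows(
    toy_model(rep("GAA", 100), gene = "GX", start = 1001L),
    toy_model(rep("AGC", 100), gene = "GY", start = 9001L,
              intron_after = 150L)
  )
  v <- dplyr::bind_rows(
    mk_variant(cds_to_genomic(models[1, ], 30L), ref = "A", alt = "T"),
    mk_variant(models$exon_end[[2]][1] + 1L, chrom = "chr1", ref = "G",
               alt = "A"),
    mk_variant(500000, ref = "C", alt = "G"),
    mk_variant(cds_to_genomic(models[1, ], 60L), ref = "AG", alt = "A")
  )
  ann <- annotate_variants(dplyr::arrange(v, chrom, pos, alt), models)
  got <- ann[order(ann$pos), ]
  expect_equal(got$gene[1:2], c("GX", "GX"))
  expect_equal(sort(got$category),
               sort(c("nonsynonymous", "frameshift_indel", "splice_donor",
                      "intergenic")))
})
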