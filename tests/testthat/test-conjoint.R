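test_that("gene intersection is the exact set intersection", {
  expect_equal(intersect_genes(c("A", "B", "C"), c("B", "C", "D")),
               c("B", "C"))
  expect_equal(intersect_genes(c("A", "B"), c("C", "D")), character())
  expect_equal(intersect_genes(c("A", "A", "B"), c("A")), "A")
})

test_that("hypergeometric enrichment matches exhaustive tail summation", {
  bg <- sprintf("G%02d", 1:10)
  sets <- list(S = bg[1:5])
  res <- enrich(bg[1:4], sets, bg, ease = FALSE)  # query = 4 set members
  expect_equal(res$k, 4)
  expect_equal(res$p_value, 5 / 210)  # C(5,4)C(5,0)/C(10,4)
  expect_equal(res$p_value, hyper_tail_oracle(4, 5, 10, 4))
  res_ease <- enrich(bg[1:4], sets, bg, ease = TRUE)
  expect_equal(res_ease$p_value, hyper_tail_oracle(3, 5, 10, 4))
  expect_gte(res_ease$p_value, res$p_value)
})

test_that("zero overlap gives p = 1 exactly; EASE gives 1 for k <= 1", {
  bg <- sprintf("G%02d", 1:20)
  sets <- list(S = bg[1:5])
  expect_equal(enrich(bg[6:9], sets, bg, ease = FALSE)$p_value, 1)
  expect_equal(enrich(c(bg[1], bg[6]), sets, bg, ease = TRUE)$p_value, 1)
})

test_that("enrichment input contracts are enforced", {
  bg <- c("A", "B")
  expect_error(enrich("A", list(S = "A"), character()), "background is empty")
  expect_error(enrich(c("A", "Z"), list(S = "A"), bg), "absent.*Z")
})

test_that("enrichment equals the brute-force oracle across an (N,K,n,k) grid", {
  N <- 60
  bg <- sprintf("G%02d", 1:N)
  for (K in c(1, 5, 20, 40)) {
    for (n in c(1, 10, 30)) {
      for (k in unique(c(0, 1, 2, min(n, K)))) {
        if (k > min(n, K) || (n - k) > (N - K)) next
        query <- c(bg[seq_len(k)], bg[K + seq_len(n - k)])
        sets <- list(S = bg[seq_len(K)])
        plain <- enrich(query, sets, bg, ease = FALSE)
        expect_equal(plain$p_value, hyper_tail_oracle(k, K, N, n),
                     tolerance = 1e-12, info = sprintf("K=%d n=%d k=%d", K, n, k))
        easep <- enrich(query, sets, bg, ease = TRUE)
        expect_equal(easep$p_value,
                     if (k <= 1) 1 else hyper_tail_oracle(k - 1, K, N, n),
                     tolerance = 1e-12)
        expect_gte(easep$p_value, plain$p_value - 1e-14)
      }
    }
  }
})

test_that("the oracle pmf normalizes and p is non-increasing in k", {
  for (case in list(c(30, 7, 10), c(60, 20, 15), c(45, 3, 40))) {
    N <- case[1]; K <- case[2]; n <- case[3]
    pmf_sum <- sum(vapply(0:min(n, K), function(x) {
      choose(K, x) * choose(N - K, n - x)
    }, numeric(1))) / choose(N, n)
    expect_equal(pmf_sum, 1, tolerance = 1e-12)
    tails <- vapply(0:min(n, K), hyper_tail_oracle, numeric(1), K = K,
                    N = N, n = n)
    expect_true(all(diff(tails) <= 1e-14))
    bg <- sprintf("G%02d", 1:N)
    for (k in 0:min(n, K)) {
      if ((n - k) > (N - K)) next
      query <- c(bg[seq_len(k)], bg[K + seq_len(n - k)])
      expect_equal(enrich(query, list(S = bg[seq_len(K)]), bg,
                          ease = FALSE)$p_value,
                   tails[k + 1], tolerance = 1e-12)
    }
  }
})

test_that("compound heterozygotes are flagged with all carried pairs", {
  v <- dplyr::bind_rows(
    mk_variant(100, gts = c(P1 = "0/1", P2 = "0/1", P3 = "0/0")),
    mk_variant(200, ref = "G", alt = "C",
               gts = c(P1 = "0/1", P2 = "0/0", P3 = "0/1")),
    mk_variant(300, ref = "C", alt = "G",
               gts = c(P1 = "0/1", P2 = "0/0", P3 = "1/1"))
  )
  ch <- compound_het(v)
  # P1 is het for 3 variants: C(3,2) = 3 pairs; P2 and P3 carry < 2 hets
  expect_equal(nrow(ch), 3)
  expect_equal(unique(ch$individual_id), "P1")
  one <- compound_het(v[1, ])
  expect_equal(nrow(one), 0)
})

conjoint_fixture <- function() {
  # two candidate variants in genes GA (full pass) and GB (not a DEG)
  bg <- sprintf("BGG%02d", 1:50)
  cand <- dplyr::bind_rows(
    mk_variant(100, gts = c(S1 = "0/1", S2 = "0/1"),
               polyphen2 = "damaging", phylop = "conserved"),
    mk_variant(900, ref = "G", alt = "A",
               gts = c(S1 = "0/1", S2 = "0/1"),
               polyphen2 = "damaging", phylop = "conserved")
  )
  cand$family_id <- "F1"
  cand$gene <- c("GA", "GB")
  cand$category <- "nonsynonymous"
  cand$hgvs_c <- c("c.1A>T", "c.2G>A")
  cand$hgvs_p <- c("p.K1*", "p.R1Q")
  deg <- tibble::tibble(gene = c("GA", "XX"),
                        log2_fold_change = c(3, -2), t_stat = c(30, -20),
                        df = c(9, 9), p_value = c(1e-8, 1e-8),
                        q_value = c(1e-7, 1e-7), is_deg = TRUE)
  sets <- list(PATH = "GA")  # k=1, K=1, n=1, N=53: p = 1/53 < 0.05
  background <- c("GA", "GB", "XX", bg)
  params <- filter_params(ease_mode = FALSE)
  enr <- enrich(intersect_genes(cand$gene, deg$gene[deg$is_deg]), sets,
                background, ease = FALSE)
  list(cand = cand, deg = deg, sets = sets, params = params, enr = enr)
}

test_that("the final report is the conjunction of all prioritization stages", {
  fx <- conjoint_fixture()
  expect_lte(fx$enr$q_value[1], 0.05)
  rep <- build_report(fx$cand, fx$deg, fx$enr, fx$sets, fx$params)
  expect_equal(rep$report$gene, "GA")
  expect_equal(rep$intersection_genes, "GA")
  expect_equal(rep$carriers$individual_id, c("S1", "S2"))
  # GB fails only the DEG conjunct: ablating it admits GB if enrichment
  # membership is also relaxed
  rep2 <- build_report(fx$cand, fx$deg, fx$enr, fx$sets, fx$params,
                       require_deg = FALSE, require_enrichment = FALSE)
  expect_equal(sort(rep2$report$gene), c("GA", "GB"))
})

test_that("LoF categories pass damage without predictor votes", {
  fx <- conjoint_fixture()
  cand <- fx$cand[1, ]
  cand$polyphen2 <- NA_character_
  cand$phylop <- NA_character_
  cand$category <- "splice_donor"
  rep <- build_report(cand, fx$deg, fx$enr, fx$sets, fx$params)
  expect_equal(nrow(rep$report), 1)
  cand$category <- "nonsynonymous"  # no votes: consensus now required
  rep0 <- build_report(cand, fx$deg, fx$enr, fx$sets, fx$params)
  expect_equal(nrow(rep0$report), 0)
})

test_that("relaxing thresholds never removes a reported variant", {
  fx <- conjoint_fixture()
  strict <- build_report(fx$cand, fx$deg, fx$enr, fx$sets, fx$params)
  lax_params <- filter_params(ease_mode = FALSE, damaging_min_votes = 1,
                              enrich_alpha = 0.2)
  lax <- build_report(fx$cand, fx$deg, fx$enr, fx$sets, lax_params)
  key <- function(r) famseg::variant_key(r$report$chrom, r$report$pos,
                                         r$report$ref, r$report$alt)
  expect_true(all(key(strict) %in% key(lax)))
})

test_that("tidy and glance summarise a report", {
  fx <- conjoint_fixture()
  rep <- build_report(fx$cand, fx$deg, fx$enr, fx$sets, fx$params)
  td <- tidy(rep)
  expect_equal(td$enriched_sets, "PATH")
  gl <- glance(rep)
  expect_equal(gl$n_final_variants, 1L)
  expect_equal(gl$n_intersection_genes, 1L)
})
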