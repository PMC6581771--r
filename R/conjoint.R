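# Conjoint prioritization: intersection of segregation candidates with
# DEGs, gene-set over-representation (hypergeometric / EASE), predictor-
# consensus prioritization, compound-heterozygote flagging, final report.

#' Intersection of candidate and DEG gene sets
#' @param candidate_genes,deg_genes Character vectors of gene symbols.
#' @return Sorted character vector of the exact set intersection.
#' @export
intersect_genes <- function(candidate_genes, deg_genes) {
  sort(intersect(unique(candidate_genes), unique(deg_genes)))
}

#' Gene-set over-representation test
#'
#' One-tailed hypergeometric tail `P(X >= k)` per set, with universe size
#' `N = |background|`, set size `K = |set `\eqn{\cap}` background|`, query
#' size `n` and overlap `k`. With `ease = TRUE` the EASE score is computed
#' instead: the tail with one hit removed, `P(X >= k - 1)` (and p = 1 when
#' `k <= 1`) — the conservative variant used by DAVID. P-values are
#' BH-adjusted across sets and results are sorted by p.
#'
#' @param query Character vector of genes; must be a subset of `background`.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param background Character vector: the gene universe. Empty background
#'   or query genes outside it are errors.
#' @param ease Use the EASE variant (default `TRUE`).
#' @return Tibble of class `famseg_enrich`: `set_name`, `k`, `n`, `K`, `N`,
#'   `p_value`, `q_value`, plus the member genes hit (`hits` list-column).
#' @export
enrich <- function(query, sets, background, ease = TRUE) {
  background <- unique(background)
  if (length(background) == 0) abort("enrichment background is empty")
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    abort(paste0("query genes absent from background: ",
                 paste(outside, collapse = ", ")))
  }
  if (is.null(names(sets)) || length(sets) == 0) {
    abort("sets must be a nonempty named list")
  }
  N <- length(background)
  n <- length(query)
  rows <- imap(sets, function(genes, nm) {
    S <- intersect(unique(genes), background)
    hits <- intersect(query, S)
    k <- length(hits); K <- length(S)
    p <- if (ease) {
      if (k <= 1) 1 else phyper(k - 2, K, N - K, n, lower.tail = FALSE)
    } else {
      if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    }
    tibble(set_name = nm, k = k, n = n, K = K, N = N, p_value = p,
           hits = list(sort(hits)))
  })
  out <- bind_rows(rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- arrange(out, .data$p_value, .data$set_name)
  out <- select(out, "set_name", "k", "n", "K", "N", "p_value", "q_value",
                "hits")
  class(out) <- c("famseg_enrich", class(out))
  out
}

#' Compound-heterozygote carriers among reported variants
#'
#' Flags individuals heterozygous for two or more distinct final-report
#' variants (any gene pair, phase ignored) and lists every carried pair —
#' candidates for greater clinical severity.
#'
#' @param variants Variant tibble (typically the final report's variants).
#' @return Tibble: `individual_id`, `variant_1`, `variant_2` (canonical
#'   keys; one row per unordered pair).
#' @export
compound_het <- function(variants) {
  assert_variants(variants)
  empty <- tibble(individual_id = character(), variant_1 = character(),
                  variant_2 = character())
  if (nrow(variants) < 2) return(empty)
  keys <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  ids <- unique(unlist(map(variants$genotypes, "sample_id")))
  rows <- list()
  for (id in ids) {
    het <- keys[gt_of(variants, id) == "0/1"]
    het <- sort(unique(het[!is.na(het)]))
    if (length(het) >= 2) {
      pairs <- combn(het, 2)
      rows[[id]] <- tibble(individual_id = id,
                           variant_1 = pairs[1, ], variant_2 = pairs[2, ])
    }
  }
  if (length(rows) == 0) return(empty)
  arrange(bind_rows(rows), .data$individual_id, .data$variant_1,
          .data$variant_2)
}

#' Build the final candidate report
#'
#' The conjoint conjunction: a co-segregating candidate variant enters the
#' final report when its gene is differentially expressed, its gene belongs
#' to at least one significantly enriched set (q <= `enrich_alpha`), and it
#' passes the damage assessment — predictor consensus
#' (`damaging_min_votes`) for substitution-type consequences, while
#' loss-of-function categories (splice donor/acceptor, frameshift, stop
#' gained) qualify by category since canonical splice disruption is their
#' computed damage call. Each conjunct can be switched off for ablation.
#' Carrier genotypes and compound-heterozygote pairs are attached;
#' compound-het carriers are flagged as candidates for more severe disease.
#'
#' @param candidates Annotated candidate tibble with a `family_id` column
#'   (the union of per-family co-segregating variants).
#' @param deg Result of [deg_test()].
#' @param enrichment Result of [enrich()] run on the candidate/DEG
#'   intersection.
#' @param sets The gene-set list used for `enrichment` (membership source).
#' @param params [filter_params()] list.
#' @param require_deg,require_enrichment,require_consensus Ablation
#'   switches; all `TRUE` by default.
#' @return List of class `famseg_report`: `report` (final variant tibble
#'   with `in_deg`, `enriched_sets`, `damage_pass` columns, ordered by
#'   family, chrom, pos), `carriers`, `compound_het`, `intersection_genes`,
#'   `enriched_set_names`.
#' @export
build_report <- function(candidates, deg, enrichment, sets,
                         params = filter_params(),
                         require_deg = TRUE, require_enrichment = TRUE,
                         require_consensus = TRUE) {
  assert_columns(candidates, c("family_id", "gene", "category"), "candidates")
  dg <- deg_genes(deg)
  inter <- intersect_genes(candidates$gene, dg)
  sig_sets <- enrichment$set_name[enrichment$q_value <= params$enrich_alpha]
  enriched_genes <- unique(unlist(sets[sig_sets])) %||% character()
  lof <- c("splice_donor", "splice_acceptor", "frameshift_indel", "stop_gained")
  damage_pass <- candidates$category %in% lof |
    predictor_consensus(candidates, params$damaging_min_votes)
  keep <- rep(TRUE, nrow(candidates))
  if (require_deg) keep <- keep & candidates$gene %in% dg
  if (require_enrichment) keep <- keep & candidates$gene %in% enriched_genes
  if (require_consensus) keep <- keep & damage_pass
  report <- candidates[keep, ]
  report$in_deg <- report$gene %in% dg
  report$damage_pass <- damage_pass[keep]
  report$enriched_sets <- map(report$gene, function(g) {
    sig_sets[map_lgl(sets[sig_sets], function(s) g %in% s)]
  })
  report <- arrange(report, .data$family_id, .data$chrom, .data$pos)
  carriers <- if (nrow(report) == 0) {
    tibble(variant = character(), individual_id = character(), gt = character())
  } else {
    bind_rows(map(seq_len(nrow(report)), function(i) {
      g <- report$genotypes[[i]]
      g <- g[g$gt %in% c("0/1", "1/1"), , drop = FALSE]
      tibble(variant = variant_key(report$chrom[i], report$pos[i],
                                   report$ref[i], report$alt[i]),
             individual_id = g$sample_id, gt = g$gt)
    }))
  }
  distinct_report <- distinct(report, .data$chrom, .data$pos, .data$ref,
                              .data$alt, .keep_all = TRUE)
  out <- list(report = report,
              carriers = carriers,
              compound_het = compound_het(distinct_report),
              intersection_genes = inter,
              enriched_set_names = sig_sets)
  class(out) <- "famseg_report"
  out
}

#' @export
print.famseg_report <- function(x, ...) {
  cat("famseg candidate report\n")
  cat("  final variants:", nrow(distinct(x$report, .data$chrom, .data$pos,
                                         .data$ref, .data$alt)), "\n")
  cat("  candidate x DEG intersection:", length(x$intersection_genes),
      "genes\n")
  cat("  enriched sets:", paste(x$enriched_set_names, collapse = ", "), "\n")
  cat("  compound-het carriers:",
      length(unique(x$compound_het$individual_id)), "\n")
  invisible(x)
}

#' @rdname build_report
#' @param x A `famseg_report`.
#' @param ... Unused.
#' @method tidy famseg_report
#' @export
tidy.famseg_report <- function(x, ...) {
  rep <- x$report
  tibble(
    family_id = rep$family_id, chrom = rep$chrom, pos = rep$pos,
    ref = rep$ref, alt = rep$alt, gene = rep$gene, category = rep$category,
    hgvs_c = rep$hgvs_c, hgvs_p = rep$hgvs_p,
    in_deg = rep$in_deg, damage_pass = rep$damage_pass,
    enriched_sets = map_chr(rep$enriched_sets, paste, collapse = ";")
  )
}

#' @rdname build_report
#' @method glance famseg_report
#' @export
glance.famseg_report <- function(x, ...) {
  tibble(
    n_final_variants = nrow(distinct(x$report, .data$chrom, .data$pos,
                                     .data$ref, .data$alt)),
    n_intersection_genes = length(x$intersection_genes),
    n_enriched_sets = length(x$enriched_set_names),
    n_compound_het_carriers = length(unique(x$compound_het$individual_id))
  )
}
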