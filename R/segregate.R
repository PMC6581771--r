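# Pedigree-aware filtering: known-variant exclusion, affected parent-child
# heterozygous co-segregation, per-individual NS/SS/I counts, and
# cross-family shared-gene detection.

#' Split variants into novel and database-known
#'
#' A variant is "known" when its exact (chrom, pos, ref, alt) key is present
#' in the exclusion list (the dbSNP / 1000 Genomes stand-in); candidate
#' variants must be absent from it.
#'
#' @param variants Variant tibble.
#' @param known Known-variant tibble from [read_known_set()].
#' @return List with tibbles `novel` and `known_hits` partitioning the input.
#' @export
filter_known <- function(variants, known) {
  assert_variants(variants)
  key_v <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  key_k <- variant_key(known$chrom, known$pos, known$ref, known$alt)
  hit <- key_v %in% key_k
  list(novel = variants[!hit, ], known_hits = variants[hit, ])
}

#' Affected parent-child pairs of one family
#' @param pedigree Pedigree tibble from [read_ped()].
#' @param family_id Family to inspect.
#' @return Tibble with columns `parent_id`, `child_id` (both affected).
#' @export
affected_pairs <- function(pedigree, family_id) {
  fam <- pedigree[pedigree$family_id == family_id, ]
  if (nrow(fam) == 0) abort(paste0("no such family in pedigree: ", family_id))
  aff <- fam$individual_id[!is.na(fam$affected) & fam$affected]
  out <- list()
  for (i in seq_len(nrow(fam))) {
    child <- fam$individual_id[i]
    if (!(child %in% aff)) next
    for (p in c(fam$father_id[i], fam$mother_id[i])) {
      if (!is.na(p) && p %in% aff) {
        out[[length(out) + 1]] <- tibble(parent_id = p, child_id = child)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(parent_id = character(), child_id = character()))
  }
  bind_rows(out)
}

#' Variants co-segregating in an affected parent-child pair
#'
#' Retains variants for which at least one affected parent-child pair of the
#' family has BOTH members heterozygous for the alternate allele (the strict
#' heterozygous transmission model; homozygous-alt carriers qualify only
#' when `allow_hom = TRUE`). Unaffected carriers elsewhere in the family do
#' not disqualify a variant at this stage. Families where both parents are
#' affected qualify through any affected pair.
#'
#' @param variants Variant tibble (any stage of the cascade).
#' @param pedigree Pedigree tibble.
#' @param family_id Family to analyse; it must contain at least one affected
#'   parent-child pair, otherwise this is a contract error.
#' @param allow_hom Accept `1/1` as carrying (default `FALSE`).
#' @return The retained subset of `variants`.
#' @export
affected_pair_shared <- function(variants, pedigree, family_id,
                                 allow_hom = FALSE) {
  assert_variants(variants)
  pairs <- affected_pairs(pedigree, family_id)
  if (nrow(pairs) == 0) {
    abort(sprintf("family %s has no affected parent-child pair", family_id))
  }
  ok_gt <- if (allow_hom) c("0/1", "1/1") else "0/1"
  keep <- map_lgl(variants$genotypes, function(g) {
    gt <- setNames(g$gt, g$sample_id)
    any(gt[pairs$parent_id] %in% ok_gt & gt[pairs$child_id] %in% ok_gt,
        na.rm = TRUE)
  })
  variants[keep, ]
}

#' Count NS/SS/I variants carried by one individual
#'
#' Counts annotated variants in the retained functional classes
#' (see [is_nssi()]) for which the individual carries at least one alternate
#' allele. Intended to be applied after quality and known-set filtering,
#' mirroring per-individual cascade counts.
#'
#' @param annotated Variant tibble with a `category` column (from
#'   [annotate_variants()]).
#' @param individual_id Sample to count; unknown ids are an error.
#' @return Integer count.
#' @export
count_nssi <- function(annotated, individual_id) {
  assert_columns(annotated, "category", "annotated variants")
  known_ids <- unique(unlist(map(annotated$genotypes, "sample_id")))
  if (nrow(annotated) > 0 && !(individual_id %in% known_ids)) {
    abort(paste0("unknown individual id: ", individual_id))
  }
  sum(is_nssi(annotated$category) & carries_alt(annotated, individual_id))
}

#' Genes with qualifying variants in multiple families
#'
#' Groups per-family candidate genes and selects those hit in at least
#' `min_families` distinct families.
#'
#' @param per_family Tibble with columns `family_id` and `gene`, one row per
#'   qualifying (shared, novel, NS/SS/I) variant or gene occurrence.
#' @param min_families Minimum number of distinct families (default 2).
#' @return List with `by_gene` (tibble: `gene`, `n_families`, `families`
#'   list-column, `selected`) and `selected_genes` (character vector).
#' @export
cross_family_genes <- function(per_family, min_families = 2L) {
  assert_columns(per_family, c("family_id", "gene"), "per-family candidates")
  by_gene <- per_family |>
    filter(!is.na(.data$gene)) |>
    distinct(.data$gene, .data$family_id) |>
    group_by(.data$gene) |>
    summarise(n_families = dplyr::n_distinct(.data$family_id),
              families = list(sort(unique(.data$family_id))),
              .groups = "drop") |>
    mutate(selected = .data$n_families >= min_families) |>
    arrange(dplyr::desc(.data$n_families), .data$gene)
  list(by_gene = by_gene,
       selected_genes = sort(by_gene$gene[by_gene$selected]))
}

#' Per-family candidate summary
#'
#' Bundles, for one family: the co-segregating candidate variants (with
#' their consequences), the genes they hit, and per-individual NS/SS/I
#' counts — one row of the published cascade table.
#'
#' @param annotated Annotated variant tibble after quality and known-set
#'   filtering.
#' @param pedigree Pedigree tibble.
#' @param family_id Family to summarise.
#' @param allow_hom Passed to [affected_pair_shared()].
#' @return List with `family_id`, `per_individual_nssi_counts` (named
#'   integer), `shared_variants` (tibble), `shared_genes` (character).
#' @export
family_candidates <- function(annotated, pedigree, family_id,
                              allow_hom = FALSE) {
  fam <- pedigree[pedigree$family_id == family_id, ]
  nssi <- annotated[is_nssi(annotated$category), ]
  shared <- affected_pair_shared(nssi, pedigree, family_id,
                                 allow_hom = allow_hom)
  counts <- vapply(fam$individual_id, function(id) count_nssi(annotated, id),
                   integer(1))
  list(family_id = family_id,
       per_individual_nssi_counts = counts,
       shared_variants = shared,
       shared_genes = sort(unique(shared$gene[!is.na(shared$gene)])))
}
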