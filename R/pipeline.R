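# End-to-end orchestration: formats -> cluster/quality filters -> annotation
# -> NS/SS/I -> known-set exclusion -> affected-pair sharing -> cross-family
# genes -> differential expression -> conjoint intersection + enrichment ->
# final report, with a cascade-style run summary.

#' Run the full prioritization cascade
#'
#' Executes every stage of the family-based prioritization pipeline on one
#' input bundle and returns the final candidate report plus a cascade
#' summary (per-individual counts per stage, mirroring the published
#' filtering table's layout). Deterministic given its inputs.
#'
#' @param paths Named list (or YAML file path) with input file paths:
#'   `vcf`, `ped`, `gene_models`, `known`, `expression`, `groups`, `gmt`.
#'   A `famseg_scenario` object is also accepted.
#' @param params [filter_params()] list.
#' @param out_dir Optional output directory; when given, writes
#'   `report.tsv`, `summary.json`, `removed.tsv`, `deg.tsv` and
#'   `enrichment.tsv`.
#' @return List of class `famseg_run`: `report` (a `famseg_report`),
#'   `summary` (list), `deg`, `enrichment`, `candidates`, `cross_family`.
#' @export
run_pipeline <- function(paths, params = filter_params(), out_dir = NULL) {
  if (inherits(paths, "famseg_scenario")) paths <- paths$paths
  if (is.character(paths) && length(paths) == 1) {
    paths <- yaml::read_yaml(paths)
  }
  need <- c("vcf", "ped", "gene_models", "known", "expression", "groups",
            "gmt")
  miss <- setdiff(need, names(paths))
  if (length(miss) > 0) {
    abort(paste0("pipeline config lacks input path(s): ",
                 paste(miss, collapse = ", ")))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  variants <- stage("read_vcf", read_vcf(paths$vcf))
  ped <- stage("read_ped", read_ped(paths$ped))
  models <- stage("read_gene_models", read_gene_models(paths$gene_models))
  known <- stage("read_known_set", read_known_set(paths$known))
  expr <- stage("read_expression", read_expression(paths$expression))
  groups <- stage("read_groups", read_groups(paths$groups))
  sets <- stage("read_gmt", read_gmt(paths$gmt))

  # site-level cluster filter over the whole cohort
  cl <- stage("filter_cluster",
              filter_cluster(variants, params$cluster_window_bp,
                             params$cluster_min_count))
  families <- unique(ped$family_id)
  removed_all <- list(cl$removed)
  per_family <- list()
  per_individual <- list()
  for (fam in families) {
    fam_ids <- ped$individual_id[ped$family_id == fam]
    q <- stage("filter_quality",
               filter_quality(cl$kept, params, samples = fam_ids))
    if (nrow(q$removed) > 0) {
      q$removed$family_id <- fam
      removed_all[[length(removed_all) + 1]] <- q$removed
    }
    ann <- stage("annotate", annotate_variants(q$kept, models))
    nssi <- ann[is_nssi(ann$category), ]
    kn <- stage("filter_known", filter_known(nssi, known))
    shared <- stage("affected_pair_shared",
                    affected_pair_shared(kn$novel, ped, fam,
                                         allow_hom = params$allow_hom))
    shared$family_id <- rep(fam, nrow(shared))
    per_family[[fam]] <- shared
    novel_ann <- kn$novel
    for (id in fam_ids) {
      per_individual[[length(per_individual) + 1]] <- tibble(
        family_id = fam, individual_id = id,
        quality_pass_carried = sum(carries_alt(q$kept, id)),
        nssi_novel = count_nssi(novel_ann, id),
        pair_shared_carried = sum(carries_alt(shared, id))
      )
    }
  }
  candidates <- bind_rows(per_family)
  per_individual <- bind_rows(per_individual)

  cross <- stage("cross_family_genes", cross_family_genes(
    candidates[!is.na(candidates$gene), c("family_id", "gene")]))

  deg <- stage("deg_test", deg_test(expr, groups, params))
  inter <- intersect_genes(candidates$gene, deg_genes(deg))
  enrichment <- stage("enrich",
                      enrich(inter, sets, background = models$gene,
                             ease = params$ease_mode))
  report <- stage("build_report",
                  build_report(candidates, deg, enrichment, sets, params))

  removed <- bind_rows(removed_all)
  summary <- list(
    n_input_variants = nrow(variants),
    n_cluster_removed = nrow(cl$removed),
    per_individual = per_individual,
    n_candidate_genes = length(unique(stats::na.omit(candidates$gene))),
    cross_family_selected = cross$selected_genes,
    n_cross_family_selected = length(cross$selected_genes),
    n_deg = sum(deg$is_deg),
    intersection_genes = inter,
    n_intersection = length(inter),
    enriched_sets = report$enriched_set_names,
    n_final_variants = nrow(distinct(report$report, .data$chrom, .data$pos,
                                     .data$ref, .data$alt)),
    compound_het_carriers = unique(report$compound_het$individual_id),
    params = unclass(params),
    input_digests = as.list(tools::md5sum(unlist(paths[need])))
  )

  out <- structure(list(report = report, summary = summary, deg = deg,
                        enrichment = enrichment, candidates = candidates,
                        cross_family = cross, removed = removed),
                   class = "famseg_run")
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tidy(run$report), file.path(out_dir, "report.tsv"))
  readr::write_tsv(run$deg, file.path(out_dir, "deg.tsv"))
  readr::write_tsv(
    mutate(run$enrichment, hits = map_chr(.data$hits, paste, collapse = ";")),
    file.path(out_dir, "enrichment.tsv"))
  removed <- run$removed
  if (nrow(removed) > 0) {
    removed <- select(removed, dplyr::any_of(c("chrom", "pos", "ref", "alt",
                                               "reason", "family_id")))
  }
  readr::write_tsv(removed, file.path(out_dir, "removed.tsv"))
  jsonlite::write_json(
    summary_for_json(run$summary),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}

summary_for_json <- function(s) {
  s$per_individual <- as.data.frame(s$per_individual)
  s
}

#' @export
print.famseg_run <- function(x, ...) {
  s <- x$summary
  cat("famseg pipeline run\n")
  cat(sprintf("  input variants:        %d\n", s$n_input_variants))
  cat(sprintf("  cluster-removed:       %d\n", s$n_cluster_removed))
  cat(sprintf("  candidate genes:       %d\n", s$n_candidate_genes))
  cat(sprintf("  cross-family genes:    %d (%s)\n", s$n_cross_family_selected,
              paste(s$cross_family_selected, collapse = ", ")))
  cat(sprintf("  DEGs:                  %d\n", s$n_deg))
  cat(sprintf("  candidate x DEG genes: %d\n", s$n_intersection))
  cat(sprintf("  enriched sets:         %s\n",
              paste(s$enriched_sets, collapse = ", ")))
  cat(sprintf("  final variants:        %d\n", s$n_final_variants))
  cat(sprintf("  compound-het carriers: %s\n",
              paste(s$compound_het_carriers, collapse = ", ")))
  invisible(x)
}

#' Tidy the final variants of a pipeline run
#' @param x A `famseg_run`.
#' @param ... Unused.
#' @return Tibble of final report variants.
#' @method tidy famseg_run
#' @export
tidy.famseg_run <- function(x, ...) tidy(x$report)

#' One-row cascade summary of a pipeline run
#' @param x A `famseg_run`.
#' @param ... Unused.
#' @return One-row tibble of stage counts.
#' @method glance famseg_run
#' @export
glance.famseg_run <- function(x, ...) {
  s <- x$summary
  tibble(
    n_input_variants = s$n_input_variants,
    n_cluster_removed = s$n_cluster_removed,
    n_candidate_genes = s$n_candidate_genes,
    n_cross_family_selected = s$n_cross_family_selected,
    n_deg = s$n_deg,
    n_intersection = s$n_intersection,
    n_enriched_sets = length(s$enriched_sets),
    n_final_variants = s$n_final_variants
  )
}
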