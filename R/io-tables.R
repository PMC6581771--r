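# Readers/writers for PED pedigrees, minimal gene models, GMT gene sets,
# expression matrices with group labels, known-variant lists and serology
# tables. All return validated tibbles (or a named list for GMT).

#' Read a 6-column PED pedigree file
#'
#' Dialect: family, individual, father, mother, sex (1 = male, 2 = female,
#' 0 = unknown), phenotype (2 = affected, 1 = unaffected, 0 or -9 = unknown).
#' Unknown parents ("0") become `NA`. Parent ids must refer to individuals of
#' the same family and the family graph must be acyclic.
#'
#' @param path Path to a PED file (whitespace- or tab-separated).
#' @return Tibble with columns `family_id`, `individual_id`, `father_id`,
#'   `mother_id`, `sex`, `affected` (logical, `NA` = unknown).
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) abort(paste0("PED file not found: ", path))
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "character"),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0) {
    return(tibble(family_id = character(), individual_id = character(),
                  father_id = character(), mother_id = character(),
                  sex = integer(), affected = logical()))
  }
  if (ncol(raw) != 6) abort("PED file must have exactly 6 columns")
  ped <- tibble(
    family_id = raw[[1]], individual_id = raw[[2]],
    father_id = ifelse(raw[[3]] == "0", NA_character_, raw[[3]]),
    mother_id = ifelse(raw[[4]] == "0", NA_character_, raw[[4]]),
    sex = as.integer(raw[[5]]),
    affected = dplyr::case_match(raw[[6]], "2" ~ TRUE, "1" ~ FALSE,
                                 .default = NA)
  )
  validate_pedigree(ped)
}

validate_pedigree <- function(ped) {
  assert_columns(ped, c("family_id", "individual_id", "father_id",
                        "mother_id", "sex", "affected"), "pedigree")
  if (anyDuplicated(ped$individual_id) > 0) {
    abort("duplicate individual ids in pedigree")
  }
  for (fam in unique(ped$family_id)) {
    sub <- ped[ped$family_id == fam, ]
    parents <- stats::na.omit(c(sub$father_id, sub$mother_id))
    dangling <- setdiff(parents, sub$individual_id)
    if (length(dangling) > 0) {
      abort(sprintf("pedigree family %s has dangling parent id(s): %s",
                    fam, paste(unique(dangling), collapse = ", ")))
    }
    # acyclicity: walk ancestors of each individual
    parent_of <- setNames(map(seq_len(nrow(sub)), function(i) {
      stats::na.omit(c(sub$father_id[i], sub$mother_id[i]))
    }), sub$individual_id)
    for (id in sub$individual_id) {
      frontier <- parent_of[[id]]
      seen <- character()
      while (length(frontier) > 0) {
        if (id %in% frontier) {
          abort(sprintf("pedigree cycle detected involving individual %s", id))
        }
        seen <- union(seen, frontier)
        frontier <- setdiff(unique(unlist(parent_of[frontier])), seen)
      }
    }
  }
  ped
}

#' Write a pedigree tibble as a 6-column PED file
#' @param ped Pedigree tibble as returned by [read_ped()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  validate_pedigree(ped)
  out <- data.frame(
    ped$family_id, ped$individual_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    ped$sex,
    ifelse(is.na(ped$affected), "0", ifelse(ped$affected, "2", "1"))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read minimal transcript models
#'
#' Tab-separated with header: `gene`, `chrom`, `strand`, `exon_starts`,
#' `exon_ends` (comma-separated 1-based closed intervals, sorted,
#' non-overlapping), `cds_start`, `cds_end`, `cds_seq` (spliced coding-strand
#' CDS sequence). One transcript per gene. The CDS length must be a positive
#' multiple of 3 and match `cds_seq`.
#'
#' @param path Path to the gene-model TSV.
#' @return Tibble with integer list-columns `exon_start`/`exon_end`.
#' @export
read_gene_models <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  assert_columns(raw, c("gene", "chrom", "strand", "exon_starts", "exon_ends",
                        "cds_start", "cds_end", "cds_seq"), "gene-model file")
  models <- tibble(
    gene = raw$gene, chrom = raw$chrom, strand = raw$strand,
    exon_start = map(strsplit(raw$exon_starts, ",", fixed = TRUE), as.integer),
    exon_end = map(strsplit(raw$exon_ends, ",", fixed = TRUE), as.integer),
    cds_start = as.integer(raw$cds_start), cds_end = as.integer(raw$cds_end),
    cds_seq = raw$cds_seq
  )
  validate_gene_models(models)
}

cds_intervals <- function(model) {
  s <- pmax(model$exon_start[[1]], model$cds_start)
  e <- pmin(model$exon_end[[1]], model$cds_end)
  keep <- s <= e
  list(start = s[keep], end = e[keep])
}

cds_length <- function(model) {
  iv <- cds_intervals(model)
  sum(iv$end - iv$start + 1)
}

validate_gene_models <- function(models) {
  assert_columns(models, c("gene", "chrom", "strand", "exon_start", "exon_end",
                           "cds_start", "cds_end", "cds_seq"), "gene models")
  if (anyDuplicated(models$gene) > 0) abort("duplicate gene symbols in models")
  if (!all(models$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    es <- m$exon_start[[1]]; ee <- m$exon_end[[1]]
    if (length(es) != length(ee) || any(is.na(es)) || any(is.na(ee))) {
      abort(sprintf("gene %s: malformed exon lists", m$gene))
    }
    if (any(ee < es)) abort(sprintf("gene %s: exon end before start", m$gene))
    if (length(es) > 1 && any(es[-1] <= ee[-length(ee)])) {
      abort(sprintf("gene %s: exons must be sorted and non-overlapping", m$gene))
    }
    len <- cds_length(m)
    if (len <= 0 || len %% 3 != 0) {
      abort(sprintf("gene %s: CDS length %d is not a positive multiple of 3",
                    m$gene, len))
    }
    if (nchar(m$cds_seq) != len) {
      abort(sprintf("gene %s: cds_seq length %d does not match CDS length %d",
                    m$gene, nchar(m$cds_seq), len))
    }
  }
  models
}

#' Write gene models as TSV
#' @param models Gene-model tibble as returned by [read_gene_models()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  validate_gene_models(models)
  out <- tibble(
    gene = models$gene, chrom = models$chrom, strand = models$strand,
    exon_starts = map_chr(models$exon_start, paste, collapse = ","),
    exon_ends = map_chr(models$exon_end, paste, collapse = ","),
    cds_start = models$cds_start, cds_end = models$cds_end,
    cds_seq = models$cds_seq
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard dialect: one set per line, `name<tab>description<tab>gene...`.
#' Parsed with `fgsea::gmtPathways()`; each set must be nonempty and genes are
#' de-duplicated within a set.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (set name -> gene symbols).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  sets <- map(sets, unique)
  if (any(lengths(sets) == 0)) abort("GMT contains an empty gene set")
  sets
}

#' Write a named list of gene sets as GMT
#' @param sets Named list of character vectors.
#' @param path Output file path.
#' @param description Description field (recycled); defaults to "na".
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("gene sets must be named")
  }
  lines <- map_chr(names(sets), function(nm) {
    paste(c(nm, description, unique(sets[[nm]])), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-sample expression matrix
#'
#' TSV with a `gene` column followed by one numeric column per sample
#' (log2-scale intensities). Duplicate genes are an error.
#'
#' @param path Path to the expression TSV.
#' @return Tibble with `gene` plus one column per sample.
#' @export
read_expression <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(expr, "gene", "expression matrix")
  if (anyDuplicated(expr$gene) > 0) {
    abort("duplicate gene symbols in expression matrix")
  }
  if (ncol(expr) < 2) abort("expression matrix has no sample columns")
  expr
}

#' Write an expression matrix as TSV
#' @param expr Expression tibble as returned by [read_expression()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Read the case/control group map for an expression matrix
#' @param path TSV with columns `sample_id`, `group` ("case" or "control").
#' @return Tibble with those two columns.
#' @export
read_groups <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  assert_columns(g, c("sample_id", "group"), "group map")
  if (!all(g$group %in% c("case", "control"))) {
    abort("group labels must be 'case' or 'control'")
  }
  g
}

#' @rdname read_groups
#' @param groups Group tibble.
#' @param path Output file path.
#' @export
write_groups <- function(groups, path) {
  readr::write_tsv(groups, path)
  invisible(path)
}

#' Read a known-variant exclusion list
#'
#' Stand-in for dbSNP/1000 Genomes membership: TSV with columns `chrom`,
#' `pos`, `ref`, `alt`. Lookup downstream is by exact key; duplicates are
#' dropped (set semantics).
#'
#' @param path Path to the known-variant TSV.
#' @return Tibble with the four key columns, de-duplicated.
#' @export
read_known_set <- function(path) {
  k <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(pos = "i", .default = "c"))
  assert_columns(k, c("chrom", "pos", "ref", "alt"), "known-variant list")
  distinct(k, .data$chrom, .data$pos, .data$ref, .data$alt)
}

#' @rdname read_known_set
#' @param known Known-variant tibble.
#' @param path Output file path.
#' @export
write_known_set <- function(known, path) {
  readr::write_tsv(distinct(known, .data$chrom, .data$pos, .data$ref, .data$alt),
                   path)
  invisible(path)
}

#' Read a serology table
#'
#' TSV with columns `subject_id`, allergen-specific IgE concentrations in
#' kU/l (at least `der_f` and `der_p` for eligibility calls), `total_ige`,
#' and 0/1 comorbidity flags (`asthma`, `eczema`, `other_allergic`,
#' `chronic_disease`, `nasal_disease`).
#'
#' @param path Path to the serology TSV.
#' @return Tibble; concentrations must be non-negative.
#' @export
read_serology <- function(path) {
  s <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(s, "subject_id", "serology table")
  num <- names(s)[vapply(s, is.numeric, logical(1))]
  conc <- setdiff(num, c("asthma", "eczema", "other_allergic",
                         "chronic_disease", "nasal_disease"))
  for (col in conc) {
    if (any(s[[col]] < 0, na.rm = TRUE)) {
      abort(sprintf("serology column %s contains negative concentrations", col))
    }
  }
  s
}

#' @rdname read_serology
#' @param serology Serology tibble.
#' @param path Output file path.
#' @export
write_serology <- function(serology, path) {
  readr::write_tsv(serology, path)
  invisible(path)
}
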