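# Consequence annotation on minimal transcript models: genomic<->CDS
# coordinate mapping, codon effects, canonical splice-site calls, HGVS
# rendering, NS/SS/I classification and predictor consensus.

NSSI_CATEGORIES <- c("nonsynonymous", "stop_gained", "stop_lost",
                     "splice_donor", "splice_acceptor",
                     "frameshift_indel", "inframe_indel")

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              `*` = "Ter")

comp_base <- function(x) chartr("ACGT", "TGCA", x)

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) abort(paste0("invalid codon: ", codon))
  aa
}

# accept a one-row tibble or a plain list as a gene model
as_model <- function(model) {
  if (is.data.frame(model)) {
    stopifnot(nrow(model) == 1)
    model <- list(gene = model$gene, chrom = model$chrom,
                  strand = model$strand,
                  exon_start = model$exon_start[[1]],
                  exon_end = model$exon_end[[1]],
                  cds_start = model$cds_start, cds_end = model$cds_end,
                  cds_seq = model$cds_seq)
  }
  model
}

model_cds_intervals <- function(m) {
  s <- pmax(m$exon_start, m$cds_start)
  e <- pmin(m$exon_end, m$cds_end)
  keep <- s <= e
  list(start = s[keep], end = e[keep])
}

# index of a genomic position along the concatenated CDS counted left-to-right
plus_cds_index <- function(iv, pos) {
  cum <- c(0, cumsum(iv$end - iv$start + 1))
  for (i in seq_along(iv$start)) {
    if (pos >= iv$start[i] && pos <= iv$end[i]) {
      return(cum[i] + pos - iv$start[i] + 1)
    }
  }
  NA_integer_
}

#' Map a genomic position to a CDS coordinate
#'
#' Exonic coding positions map to their 1-based position along the spliced
#' CDS in translation order (strand-aware). Intronic positions within the
#' gene map to the nearest exon boundary in transcript sense, with a signed
#' offset: `+k` for the k-th base after a donor site, `-k` for the k-th base
#' before an acceptor site (rendered "502+1"-style by [render_cds_coord()]).
#' Positions outside the gene return `NULL`.
#'
#' @param model One gene model (one-row tibble from [read_gene_models()] or
#'   an equivalent list).
#' @param pos 1-based genomic position on the model's chromosome.
#' @return `NULL`, or a list with `cds_pos` and `intron_offset` (0 for
#'   exonic coding positions).
#' @export
genomic_to_cds <- function(model, pos) {
  m <- as_model(model)
  span <- range(c(m$exon_start, m$exon_end))
  if (pos < span[1] || pos > span[2]) return(NULL)
  iv <- model_cds_intervals(m)
  total <- sum(iv$end - iv$start + 1)
  minus <- identical(m$strand, "-")
  exonic <- any(pos >= m$exon_start & pos <= m$exon_end)
  if (exonic) {
    pidx <- plus_cds_index(iv, pos)
    if (is.na(pidx)) return(NULL)  # exonic but non-coding (UTR): not modelled
    cds_pos <- if (minus) total - pidx + 1L else pidx
    return(list(cds_pos = as.integer(cds_pos), intron_offset = 0L))
  }
  # intronic: locate flanking exons
  prev_end <- max(m$exon_end[m$exon_end < pos])
  next_start <- min(m$exon_start[m$exon_start > pos])
  cp <- function(p) {
    pidx <- plus_cds_index(iv, p)
    if (is.na(pidx)) return(NA_integer_)
    as.integer(if (minus) total - pidx + 1L else pidx)
  }
  d_left <- pos - prev_end
  d_right <- next_start - pos
  if (!minus) {
    if (d_left <= d_right) {
      list(cds_pos = cp(prev_end), intron_offset = as.integer(d_left))
    } else {
      list(cds_pos = cp(next_start), intron_offset = as.integer(-d_right))
    }
  } else {
    # transcript runs right-to-left: the donor side of this intron is the
    # genomic-right exon's start, the acceptor side the genomic-left exon's end
    if (d_right <= d_left) {
      list(cds_pos = cp(next_start), intron_offset = as.integer(d_right))
    } else {
      list(cds_pos = cp(prev_end), intron_offset = as.integer(-d_left))
    }
  }
}

#' Map a CDS position back to its genomic position
#' @inheritParams genomic_to_cds
#' @param cds_pos 1-based position along the spliced CDS.
#' @return Integer genomic position.
#' @export
cds_to_genomic <- function(model, cds_pos) {
  m <- as_model(model)
  iv <- model_cds_intervals(m)
  total <- sum(iv$end - iv$start + 1)
  if (cds_pos < 1 || cds_pos > total) {
    abort(sprintf("cds_pos %d outside CDS of length %d", cds_pos, total))
  }
  pidx <- if (identical(m$strand, "-")) total - cds_pos + 1L else cds_pos
  cum <- c(0, cumsum(iv$end - iv$start + 1))
  i <- findInterval(pidx - 1, cum)
  as.integer(iv$start[i] + (pidx - cum[i]) - 1)
}

#' Render a CDS coordinate in HGVS style
#' @param coord List as returned by [genomic_to_cds()].
#' @return Character scalar, e.g. `"603"` or `"502+1"`.
#' @export
render_cds_coord <- function(coord) {
  if (coord$intron_offset == 0) return(as.character(coord$cds_pos))
  sign <- if (coord$intron_offset > 0) "+" else "-"
  paste0(coord$cds_pos, sign, abs(coord$intron_offset))
}

#' Protein residue index of a CDS position
#' @param cds_pos 1-based CDS position(s), >= 1.
#' @return `ceiling(cds_pos / 3)`, the 1-based codon/residue index.
#' @examples
#' residue_index(603)  # 201
#' @export
residue_index <- function(cds_pos) {
  if (any(cds_pos < 1)) abort("cds_pos must be >= 1")
  as.integer(ceiling(cds_pos / 3))
}

consequence_row <- function(gene, category, hgvs_c = NA_character_,
                            hgvs_p = NA_character_,
                            residue_index = NA_integer_) {
  tibble(gene = gene, category = category, hgvs_c = hgvs_c,
         hgvs_p = hgvs_p, residue_index = as.integer(residue_index))
}

aa_label <- function(aa, style) {
  if (style == "three") unname(AA_THREE[aa]) else aa
}

#' Annotate a single-base coding substitution
#'
#' Translates the reference and mutated codon with the standard genetic code.
#' Alleles are reported on the coding strand (complemented for minus-strand
#' models). A reference allele that disagrees with the model's CDS sequence
#' is an error, not a silent skip.
#'
#' @inheritParams genomic_to_cds
#' @param variant One-row variant tibble (or list) with `pos`, `ref`, `alt`;
#'   must be a single-base substitution inside the CDS.
#' @param hgvs_p_style `"one"` (default, e.g. "p.E201D") or `"three"`
#'   ("p.Glu201Asp").
#' @return One-row consequence tibble: `gene`, `category` (nonsynonymous,
#'   synonymous, stop_gained or stop_lost), `hgvs_c`, `hgvs_p`,
#'   `residue_index`.
#' @export
annotate_substitution <- function(model, variant, hgvs_p_style = c("one", "three")) {
  hgvs_p_style <- match.arg(hgvs_p_style)
  m <- as_model(model)
  if (nchar(variant$ref) != 1 || nchar(variant$alt) != 1) {
    abort("annotate_substitution requires a single-base substitution")
  }
  coord <- genomic_to_cds(m, variant$pos)
  if (is.null(coord) || coord$intron_offset != 0) {
    abort(sprintf("position %d is not a coding position of gene %s",
                  variant$pos, m$gene))
  }
  minus <- identical(m$strand, "-")
  ref_c <- if (minus) comp_base(variant$ref) else variant$ref
  alt_c <- if (minus) comp_base(variant$alt) else variant$alt
  if (substr(m$cds_seq, coord$cds_pos, coord$cds_pos) != ref_c) {
    abort(sprintf(
      "reference mismatch for gene %s at cds position %d: model has %s, variant ref (coding strand) is %s",
      m$gene, coord$cds_pos,
      substr(m$cds_seq, coord$cds_pos, coord$cds_pos), ref_c))
  }
  idx <- residue_index(coord$cds_pos)
  codon_start <- 3L * idx - 2L
  ref_codon <- substr(m$cds_seq, codon_start, codon_start + 2L)
  within <- coord$cds_pos - codon_start + 1L
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_c
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  category <-
    if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gained"
    else if (ref_aa == "*") "stop_lost"
    else "nonsynonymous"
  consequence_row(
    gene = m$gene, category = category,
    hgvs_c = paste0("c.", coord$cds_pos, ref_c, ">", alt_c),
    hgvs_p = paste0("p.", aa_label(ref_aa, hgvs_p_style), idx,
                    aa_label(alt_aa, hgvs_p_style)),
    residue_index = idx
  )
}

#' Classify an intronic variant at a splice site
#'
#' Canonical-dinucleotide rule: intron offsets +1/+2 are splice-donor
#' disruptions, -1/-2 splice-acceptor disruptions, anything deeper is plain
#' intronic. Splice-strength scoring is out of scope; the canonical call is
#' the computed damage assessment for splice variants.
#'
#' @inheritParams annotate_substitution
#' @return One-row consequence tibble with offset-style `hgvs_c` (e.g.
#'   `"c.502+1G>A"`); `hgvs_p` is `NA`.
#' @export
classify_splice <- function(model, variant) {
  m <- as_model(model)
  coord <- genomic_to_cds(m, variant$pos)
  if (is.null(coord) || coord$intron_offset == 0) {
    abort(sprintf("position %d is not intronic within gene %s",
                  variant$pos, m$gene))
  }
  category <- if (coord$intron_offset %in% c(1L, 2L)) "splice_donor"
  else if (coord$intron_offset %in% c(-1L, -2L)) "splice_acceptor"
  else "intronic"
  minus <- identical(m$strand, "-")
  ref_c <- if (minus) comp_base(variant$ref) else variant$ref
  alt_c <- if (minus) comp_base(variant$alt) else variant$alt
  consequence_row(
    gene = m$gene, category = category,
    hgvs_c = paste0("c.", render_cds_coord(coord), ref_c, ">", alt_c)
  )
}

#' Annotate a coding insertion or deletion
#'
#' VCF-style indels (anchor base shared between ref and alt). Length
#' difference not divisible by 3 is a frameshift, otherwise in-frame.
#'
#' @inheritParams annotate_substitution
#' @return One-row consequence tibble with del/ins-style `hgvs_c`.
#' @export
annotate_indel <- function(model, variant) {
  m <- as_model(model)
  ldiff <- nchar(variant$alt) - nchar(variant$ref)
  if (ldiff == 0) abort("annotate_indel requires an insertion or deletion")
  coord <- genomic_to_cds(m, variant$pos)
  if (is.null(coord)) {
    abort(sprintf("position %d is outside gene %s", variant$pos, m$gene))
  }
  category <- if (abs(ldiff) %% 3 != 0) "frameshift_indel" else "inframe_indel"
  anchor <- coord$cds_pos
  hgvs_c <- if (ldiff < 0) {
    d <- -ldiff
    if (d == 1) paste0("c.", anchor + 1, "del")
    else paste0("c.", anchor + 1, "_", anchor + d, "del")
  } else {
    paste0("c.", anchor, "_", anchor + 1, "ins", substr(variant$alt, 2,
                                                        nchar(variant$alt)))
  }
  consequence_row(gene = m$gene, category = category, hgvs_c = hgvs_c)
}

#' Is a consequence category in the retained NS/SS/I class?
#'
#' NS/SS/I = nonsynonymous substitutions (including stop gain/loss),
#' splice-site acceptor/donor variants, and coding insertions/deletions.
#'
#' @param category Character vector of consequence categories.
#' @return Logical vector.
#' @export
is_nssi <- function(category) {
  category %in% NSSI_CATEGORIES
}

#' Predictor-consensus damage flag
#'
#' Counts deleterious-class calls (`damaging`, `conserved`,
#' `disease_causing`) across the SIFT, PolyPhen2, PhyloP and MutationTaster
#' columns; missing predictors count as non-votes.
#'
#' @param variants Variant tibble with the four predictor-call columns.
#' @param min_votes Minimum deleterious calls for a `TRUE` flag.
#' @return Logical vector, one element per variant.
#' @export
predictor_consensus <- function(variants, min_votes = 2L) {
  deleterious <- c("damaging", "conserved", "disease_causing")
  calls <- cbind(variants$sift %in% deleterious,
                 variants$polyphen2 %in% deleterious,
                 variants$phylop %in% deleterious,
                 variants$mutation_taster %in% deleterious)
  rowSums(calls) >= min_votes
}

#' Annotate a variant table against a set of gene models
#'
#' Routes each variant to the transcript model whose exon span contains it
#' (one model per gene; first match wins), then to the appropriate
#' consequence call: coding single-base changes to
#' [annotate_substitution()], coding indels to [annotate_indel()], intronic
#' positions to [classify_splice()]. Positions outside every model are
#' `intergenic`.
#'
#' @param variants Variant tibble from [read_vcf()].
#' @param models Gene-model tibble from [read_gene_models()].
#' @inheritParams annotate_substitution
#' @return `variants` with appended columns `gene`, `category`, `hgvs_c`,
#'   `hgvs_p`, `residue_index`.
#' @export
annotate_variants <- function(variants, models, hgvs_p_style = c("one", "three")) {
  hgvs_p_style <- match.arg(hgvs_p_style)
  assert_variants(variants)
  if (nrow(variants) == 0) {
    return(dplyr::bind_cols(variants, consequence_row(character(), character(),
                                                      character(), character(),
                                                      integer())))
  }
  span_start <- map_int(models$exon_start, min)
  span_end <- map_int(models$exon_end, max)
  cons <- map(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    hit <- which(models$chrom == v$chrom & span_start <= v$pos &
                   span_end >= v$pos)
    if (length(hit) == 0) {
      return(consequence_row(NA_character_, "intergenic"))
    }
    m <- as_model(models[hit[1], ])
    coord <- genomic_to_cds(m, v$pos)
    if (is.null(coord)) return(consequence_row(m$gene, "intronic"))
    is_snv <- nchar(v$ref) == 1 && nchar(v$alt) == 1
    if (!is_snv) {
      if (coord$intron_offset == 0) return(annotate_indel(m, v))
      return(classify_splice(m, v))
    }
    if (coord$intron_offset == 0) {
      annotate_substitution(m, v, hgvs_p_style = hgvs_p_style)
    } else {
      classify_splice(m, v)
    }
  })
  dplyr::bind_cols(variants, bind_rows(cons))
}
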