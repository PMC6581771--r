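# internal helpers shared across modules

#' Canonical key for a variant allele
#'
#' Builds the `chrom:pos:ref>alt` string used to identify one site/allele pair
#' throughout reports and ground-truth bookkeeping.
#'
#' @param chrom,pos,ref,alt Vectors describing one alternate allele per element.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  if (length(chrom) == 0) return(character(0))
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

# deterministic 31-bit seed derived from a base seed and a stream name; keeps
# independent RNG streams per emitted file so adding one never perturbs others
derive_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(miss, collapse = ", ")))
  }
  invisible(df)
}

# variants must carry these columns everywhere downstream of read_vcf()
variant_cols <- c("chrom", "pos", "ref", "alt", "site_mq",
                  "sift", "polyphen2", "phylop", "mutation_taster", "genotypes")

assert_variants <- function(variants, what = "variants") {
  assert_columns(variants, variant_cols, what)
  invisible(variants)
}

is_sorted_variants <- function(variants) {
  if (nrow(variants) < 2) return(TRUE)
  o <- order(variants$chrom, variants$pos, variants$alt, method = "radix")
  identical(o, seq_len(nrow(variants)))
}

# genotype of one sample at each variant ("0/0","0/1","1/1","./.","other",
# or NA when the sample is absent from the genotype table)
gt_of <- function(variants, sample_id) {
  map_chr(variants$genotypes, function(g) {
    i <- match(sample_id, g$sample_id)
    if (is.na(i)) NA_character_ else g$gt[i]
  })
}

carries_alt <- function(variants, sample_id) {
  gt_of(variants, sample_id) %in% c("0/1", "1/1")
}
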