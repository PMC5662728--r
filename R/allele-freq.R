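#' Allele counts and frequencies per collection and locus
#'
#' Missing genotypes contribute nothing; the total at a locus is twice the
#' number of individuals scored there.  Frequencies are undefined (NA) where
#' the total is zero.
#'
#' @param geno Genotype tibble.
#' @param registry Optional registry from [locus_registry()]; defaults to the
#'   registry of `geno` itself.  Supplying a wider registry (e.g. the
#'   baseline-plus-mixture union) yields explicit zero counts for alleles a
#'   collection never shows.
#' @return Tibble `collection`, `locus`, `allele`, `count`, `total`, `freq`.
#' @export
allele_counts <- function(geno, registry = NULL) {
  check_genotypes(geno)
  registry <- registry %||% locus_registry(geno)
  pops <- unique(geno$collection)
  reg <- registry_list(registry)
  loci <- intersect(locus_order(geno), names(reg))
  cms <- count_matrices(geno, reg, pops = pops, loci = loci)
  rows <- purrr::map(loci, function(l) {
    cm <- cms[[l]]
    tot <- rowSums(cm)
    tibble(
      collection = rep(pops, times = ncol(cm)),
      locus = l,
      allele = rep(as.integer(colnames(cm)), each = length(pops)),
      count = as.integer(cm),
      total = as.integer(rep(tot, times = ncol(cm)))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$freq <- ifelse(out$total > 0, out$count / out$total, NA_real_)
  dplyr::arrange(out, .data$collection, .data$locus, .data$allele)
}
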