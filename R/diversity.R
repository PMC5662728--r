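#' Per-population genetic diversity: expected heterozygosity and allelic richness
#'
#' Expected heterozygosity is Nei's unbiased gene diversity per locus,
#' `H_S = 2n/(2n-1) * (1 - sum p^2)` with `n` the diploids scored at the
#' locus (set `unbiased = FALSE` for the plain `1 - sum p^2`).  Allelic
#' richness is the hypergeometric rarefaction to `g` gene copies,
#' `AR(g) = sum_a [1 - C(N - N_a, g) / C(N, g)]`, the expected number of
#' distinct alleles in a random subsample of `g` gene copies.  The default
#' `g = 24` corresponds to a minimum sample of 12 diploid individuals.
#'
#' @param geno Genotype tibble (one or more collections).
#' @param g Rarefaction size in gene copies (2 x individuals); default 24.
#' @param unbiased Use the small-sample-corrected gene diversity (default).
#' @param clip_g If TRUE, loci with fewer than `g` gene copies are rarefied
#'   at their own total instead of being dropped.
#' @return A tibble with one row per collection x locus (`collection`,
#'   `locus`, `n`, `n_alleles`, `h_s`, `ar`, `g_used`) plus per-collection
#'   mean rows identified by `locus == ".mean"`.
#' @export
diversity_summary <- function(geno, g = 24, unbiased = TRUE, clip_g = FALSE) {
  if (g < 1) abort("`g` must be at least 1 gene copy.")
  freqs <- allele_counts(geno)
  per <- freqs %>%
    dplyr::group_by(.data$collection, .data$locus) %>%
    dplyr::summarise(
      n = .data$total[1] / 2,
      n_alleles = sum(.data$count > 0),
      h_s = hs_one(.data$count, .data$total[1], unbiased = unbiased),
      ar = ar_one(.data$count, .data$total[1], g = g, clip = clip_g),
      g_used = if (clip_g) min(g, .data$total[1]) else g,
      .groups = "drop"
    )
  dropped <- per[is.na(per$ar) & per$n > 0, ]
  if (nrow(dropped)) {
    warn(sprintf(
      "allelic richness omitted at %d collection x locus combination(s) with fewer than g = %d gene copies.",
      nrow(dropped), g
    ))
  }
  means <- per %>%
    dplyr::group_by(.data$collection) %>%
    dplyr::summarise(
      locus = ".mean",
      n = mean(.data$n),
      n_alleles = mean(.data$n_alleles),
      h_s = mean(.data$h_s, na.rm = TRUE),
      ar = mean(.data$ar, na.rm = TRUE),
      g_used = g,
      .groups = "drop"
    )
  dplyr::bind_rows(per, means)
}

# unbiased gene diversity at one locus
hs_one <- function(counts, total, unbiased = TRUE) {
  if (is.na(total) || total == 0) return(NA_real_)
  p <- counts / total
  d <- 1 - sum(p^2)
  if (!unbiased) return(d)
  n <- total / 2
  if (2 * n - 1 <= 0) return(NA_real_)
  (2 * n / (2 * n - 1)) * d
}

# hypergeometric rarefaction of allele count to g gene copies
ar_one <- function(counts, total, g, clip = FALSE) {
  if (is.na(total) || total == 0) return(NA_real_)
  if (total < g) {
    if (!clip) return(NA_real_)
    g <- total
  }
  counts <- counts[counts > 0]
  # P(allele absent from a g-subsample) = C(N - N_a, g) / C(N, g)
  log_absent <- lchoose(total - counts, g) - lchoose(total, g)
  log_absent[total - counts < g] <- -Inf
  sum(1 - exp(log_absent))
}
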