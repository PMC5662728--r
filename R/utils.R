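# Internal helpers shared across modules.
#
# The canonical genotype container is a long tibble with columns
#   collection (chr), indiv (chr), locus (chr), allele_1 (int), allele_2 (int)
# where a missing genotype has NA in both allele columns (never just one).
# Allele labels are raw integer codes (standardized fragment sizes).

GENO_COLS <- c("collection", "indiv", "locus", "allele_1", "allele_2")

check_genotypes <- function(geno, arg = "geno") {
  if (!is.data.frame(geno)) {
    abort(sprintf("`%s` must be a data frame of genotypes.", arg))
  }
  missing_cols <- setdiff(GENO_COLS, names(geno))
  if (length(missing_cols)) {
    abort(sprintf(
      "`%s` lacks genotype column(s): %s.", arg,
      paste(missing_cols, collapse = ", ")
    ))
  }
  half <- xor(is.na(geno$allele_1), is.na(geno$allele_2))
  if (any(half)) {
    abort(sprintf(
      "`%s` has %d half-missing genotype(s); both alleles must be present or both NA.",
      arg, sum(half)
    ))
  }
  invisible(geno)
}

#' Build the locus registry of a genotype table
#'
#' The registry is the ordered set of distinct allele codes observed at each
#' locus, pooled across every collection passed in (baseline and mixture
#' alike), so that the allele-class count `k` used by the assignment prior
#' covers query alleles unobserved in any one reference population.
#'
#' @param geno A genotype tibble (`collection`, `indiv`, `locus`, `allele_1`,
#'   `allele_2`).
#' @param ... Further genotype tibbles whose alleles are unioned in.
#' @return A tibble with columns `locus`, `allele` (sorted ascending within
#'   locus) and `k` (distinct alleles at the locus).
#' @export
locus_registry <- function(geno, ...) {
  check_genotypes(geno)
  extra <- list(...)
  for (g in extra) check_genotypes(g, arg = "...")
  all_g <- dplyr::bind_rows(c(list(geno), extra))
  long <- tidyr::pivot_longer(
    all_g[, c("locus", "allele_1", "allele_2")],
    cols = c("allele_1", "allele_2"), values_to = "allele"
  )
  long <- long[!is.na(long$allele), c("locus", "allele")]
  reg <- dplyr::distinct(long)
  reg <- dplyr::arrange(reg, .data$locus, .data$allele)
  dplyr::mutate(dplyr::group_by(reg, .data$locus), k = dplyr::n()) %>%
    dplyr::ungroup()
}

# Registry as a named list of sorted integer allele vectors.
registry_list <- function(registry) {
  split(registry$allele, registry$locus)
}

# Locus order: keep first-appearance order of the genotype table.
locus_order <- function(geno) unique(geno$locus)

# Convert a genotype tibble into per-locus allele-index matrices.
# Returns list(ind = tibble(collection, indiv), loci = chr,
#              calls = named list of n x 2 integer matrices (registry indices,
#                      NA for missing))
geno_matrices <- function(geno, reg_list, loci = NULL) {
  check_genotypes(geno)
  ind <- dplyr::distinct(geno[, c("collection", "indiv")])
  key <- paste(ind$collection, ind$indiv, sep = "\r")
  loci <- loci %||% locus_order(geno)
  gkey <- paste(geno$collection, geno$indiv, sep = "\r")
  row_of <- match(gkey, key)
  calls <- vector("list", length(loci))
  names(calls) <- loci
  for (l in loci) {
    m <- matrix(NA_integer_, nrow = nrow(ind), ncol = 2L)
    sel <- geno$locus == l
    alleles <- reg_list[[l]]
    i1 <- match(geno$allele_1[sel], alleles)
    i2 <- match(geno$allele_2[sel], alleles)
    bad <- (!is.na(geno$allele_1[sel]) & is.na(i1)) |
      (!is.na(geno$allele_2[sel]) & is.na(i2))
    if (any(bad)) {
      abort(sprintf("allele code(s) at locus %s are absent from the registry", l))
    }
    m[row_of[sel], 1L] <- i1
    m[row_of[sel], 2L] <- i2
    calls[[l]] <- m
  }
  list(ind = ind, loci = loci, calls = calls)
}

# Per-population allele-count matrices: named list (locus) of P x k matrices,
# rows = populations (collections) in `pops` order.
count_matrices <- function(geno, reg_list, pops = NULL, loci = NULL) {
  pops <- pops %||% unique(geno$collection)
  loci <- loci %||% locus_order(geno)
  out <- vector("list", length(loci))
  names(out) <- loci
  pop_of <- match(geno$collection, pops)
  for (l in loci) {
    alleles <- reg_list[[l]]
    k <- length(alleles)
    cm <- matrix(0, nrow = length(pops), ncol = k,
                 dimnames = list(pops, alleles))
    sel <- which(geno$locus == l & !is.na(geno$allele_1) & !is.na(pop_of))
    if (length(sel)) {
      p <- pop_of[sel]
      a1 <- match(geno$allele_1[sel], alleles)
      a2 <- match(geno$allele_2[sel], alleles)
      tab <- tabulate(c((p - 1L) * k + a1, (p - 1L) * k + a2),
                      nbins = length(pops) * k)
      cm[] <- matrix(tab, nrow = length(pops), ncol = k, byrow = TRUE)
    }
    out[[l]] <- cm
  }
  out
}

# Dirichlet sampler via gamma draws; rows are independent draws.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  sums <- rowSums(x)
  # guard degenerate all-zero draws (tiny alphas): fall back to one-hot
  zero <- sums == 0
  if (any(zero)) {
    for (i in which(zero)) {
      x[i, sample.int(k, 1L)] <- 1
    }
    sums <- rowSums(x)
  }
  x / sums
}

# Run `expr` under a local RNG seed when `seed` is non-NULL.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) force(expr) else withr::with_seed(as.integer(seed), expr)
}

# Derive a stage sub-seed from a global seed; stays below 2^31.
substream <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483629) + 1L
}

# log(sum(exp(x))) by rows of a matrix, guarding -Inf rows.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx_safe <- ifelse(is.finite(mx), mx, 0)
  mx_safe + log(rowSums(exp(m - mx_safe)))
}

# G log-likelihood-ratio statistic of a contingency table (zero cells skipped).
g_statistic <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n == 0) return(0)
  e <- outer(rowSums(tab), colSums(tab)) / n
  keep <- tab > 0
  2 * sum(tab[keep] * log(tab[keep] / e[keep]))
}
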