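# Permutation tests for genic differentiation, heterozygote deficit (F_IS)
# and composite linkage disequilibrium.  All p-values use the add-one rule
# p = (1 + #{perm >= obs}) / (n_perm + 1), so p is in (0, 1] and never zero.

#' Permutation test of genic differentiation between two collections
#'
#' The statistic is the sum over loci of the G log-likelihood-ratio of the
#' 2 x k allele-count table; the null distribution is built by permuting
#' whole multilocus genotypes (individuals) between the two collections, so
#' within-individual and between-locus associations are preserved under the
#' null of identical allele frequencies.
#'
#' @param geno Genotype tibble containing both collections.
#' @param pop_a,pop_b Collection ids to compare.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional RNG seed for reproducibility.
#' @return A tibble with `pop_a`, `pop_b`, `statistic`, `p_value`, `n_perm`,
#'   `seed`; attribute `"per_locus"` holds per-locus G and p.
#' @export
genic_differentiation_test <- function(geno, pop_a, pop_b, n_perm = 999,
                                       seed = NULL) {
  check_genotypes(geno)
  if (n_perm < 99) abort("`n_perm` must be at least 99.")
  sub <- geno[geno$collection %in% c(pop_a, pop_b), ]
  if (!nrow(sub[sub$collection == pop_a, ]) || !nrow(sub[sub$collection == pop_b, ])) {
    abort("both collections must be non-empty.")
  }
  registry <- locus_registry(sub)
  reg <- registry_list(registry)
  loci <- locus_order(sub)
  gm <- geno_matrices(sub, reg, loci)
  in_a <- gm$ind$collection == pop_a
  n_ind <- nrow(gm$ind)

  # per-locus individual x allele dose matrices
  dose <- lapply(loci, function(l) {
    cm <- gm$calls[[l]]
    k <- length(reg[[l]])
    d <- matrix(0L, n_ind, k)
    ok <- which(!is.na(cm[, 1]))
    if (length(ok)) {
      d[cbind(ok, cm[ok, 1])] <- d[cbind(ok, cm[ok, 1])] + 1L
      d[cbind(ok, cm[ok, 2])] <- d[cbind(ok, cm[ok, 2])] + 1L
    }
    d
  })
  names(dose) <- loci

  stat_for <- function(is_a) {
    per <- vapply(loci, function(l) {
      d <- dose[[l]]
      tab <- rbind(colSums(d[is_a, , drop = FALSE]),
                   colSums(d[!is_a, , drop = FALSE]))
      g_statistic(tab)
    }, numeric(1))
    per
  }

  obs_per <- stat_for(in_a)
  obs <- sum(obs_per)
  perm_per <- with_seed_if(seed, {
    m <- matrix(0, n_perm, length(loci))
    for (i in seq_len(n_perm)) m[i, ] <- stat_for(sample(in_a))
    m
  })
  p <- (1 + sum(rowSums(perm_per) >= obs - 1e-12)) / (n_perm + 1)
  p_locus <- (1 + colSums(sweep(perm_per, 2, obs_per - 1e-12, ">="))) / (n_perm + 1)
  out <- tibble(pop_a = pop_a, pop_b = pop_b, statistic = obs, p_value = p,
                n_perm = n_perm, seed = seed %||% NA_integer_)
  attr(out, "per_locus") <- tibble(locus = loci, g = obs_per, p_value = p_locus)
  out
}

#' One-sided permutation test for heterozygote deficit (F_IS > 0)
#'
#' The multilocus statistic is `f = 1 - sum_l H_obs,l / sum_l H_exp,l`
#' (observed vs unbiased expected heterozygosity pooled over loci); the null
#' randomizes alleles among individuals within the collection, locus by
#' locus, which enforces Hardy-Weinberg proportions while keeping allele
#' frequencies fixed.  One-sided: large positive f (deficit) is extreme.
#'
#' @param geno Genotype tibble.
#' @param pop Collection id to test.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional RNG seed.
#' @return Tibble `pop`, `statistic`, `p_value`, `n_perm`, `seed`,
#'   `monomorphic` (TRUE forces p = 1).
#' @export
permutation_fis_test <- function(geno, pop, n_perm = 999, seed = NULL) {
  check_genotypes(geno)
  if (n_perm < 99) abort("`n_perm` must be at least 99.")
  sub <- geno[geno$collection == pop & !is.na(geno$allele_1), ]
  if (!nrow(sub)) abort("collection is empty or entirely missing.")
  loci <- locus_order(sub)
  allele_sets <- lapply(loci, function(l) {
    s <- sub[sub$locus == l, ]
    list(a = c(s$allele_1, s$allele_2), n = nrow(s))
  })
  names(allele_sets) <- loci
  poly <- vapply(allele_sets, function(x) length(unique(x$a)) > 1L, logical(1))
  if (!any(poly)) {
    return(tibble(pop = pop, statistic = NA_real_, p_value = 1,
                  n_perm = n_perm, seed = seed %||% NA_integer_,
                  monomorphic = TRUE))
  }

  f_from_pairs <- function(a1, a2, n) {
    # observed het count and unbiased expected het for one locus
    tot <- 2 * n
    cnt <- table(c(a1, a2))
    h_exp <- (tot / (tot - 1)) * (1 - sum((cnt / tot)^2)) * n
    h_obs <- sum(a1 != a2)
    c(h_obs, h_exp)
  }
  stat <- function(pairs_fun) {
    ho <- he <- 0
    for (l in loci[poly]) {
      x <- allele_sets[[l]]
      p <- pairs_fun(x)
      hh <- f_from_pairs(p[[1]], p[[2]], x$n)
      ho <- ho + hh[1]
      he <- he + hh[2]
    }
    1 - ho / he
  }
  obs <- stat(function(x) {
    list(x$a[seq_len(x$n)], x$a[x$n + seq_len(x$n)])
  })
  perm_stats <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(i) {
      stat(function(x) {
        sh <- sample(x$a)
        list(sh[seq_len(x$n)], sh[x$n + seq_len(x$n)])
      })
    }, numeric(1))
  })
  p <- (1 + sum(perm_stats >= obs - 1e-12)) / (n_perm + 1)
  tibble(pop = pop, statistic = obs, p_value = p, n_perm = n_perm,
         seed = seed %||% NA_integer_, monomorphic = FALSE)
}

#' Permutation test for composite linkage disequilibrium between two loci
#'
#' The statistic is the G log-likelihood-ratio of the two-locus genotype
#' contingency table (unordered genotypes as categories); the null permutes
#' the second locus's genotypes among individuals, breaking any association
#' while preserving both single-locus genotype distributions.
#'
#' @param geno Genotype tibble.
#' @param pop Collection id.
#' @param locus_a,locus_b Locus names.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional RNG seed.
#' @return Tibble `pop`, `locus_a`, `locus_b`, `statistic`, `p_value`,
#'   `n_perm`, `seed`, `monomorphic`.
#' @export
ld_permutation_test <- function(geno, pop, locus_a, locus_b, n_perm = 999,
                                seed = NULL) {
  check_genotypes(geno)
  if (n_perm < 99) abort("`n_perm` must be at least 99.")
  sub <- geno[geno$collection == pop, ]
  ga <- sub[sub$locus == locus_a, ]
  gb <- sub[sub$locus == locus_b, ]
  gb <- gb[match(ga$indiv, gb$indiv), ]
  ok <- !is.na(ga$allele_1) & !is.na(gb$allele_1)
  ga <- ga[ok, ]
  gb <- gb[ok, ]
  gt <- function(g) paste(pmin(g$allele_1, g$allele_2),
                          pmax(g$allele_1, g$allele_2), sep = "/")
  A <- gt(ga)
  B <- gt(gb)
  if (length(unique(A)) < 2L || length(unique(B)) < 2L) {
    return(tibble(pop = pop, locus_a = locus_a, locus_b = locus_b,
                  statistic = NA_real_, p_value = 1, n_perm = n_perm,
                  seed = seed %||% NA_integer_, monomorphic = TRUE))
  }
  obs <- g_statistic(table(A, B))
  perm_stats <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(i) g_statistic(table(A, sample(B))),
           numeric(1))
  })
  p <- (1 + sum(perm_stats >= obs - 1e-12)) / (n_perm + 1)
  tibble(pop = pop, locus_a = locus_a, locus_b = locus_b, statistic = obs,
         p_value = p, n_perm = n_perm, seed = seed %||% NA_integer_,
         monomorphic = FALSE)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Nominal family-wise significance level.
#' @param n_tests Number of tests in the family (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_alpha <- function(alpha, n_tests) {
  if (n_tests < 1) abort("`n_tests` must be at least 1.")
  alpha / n_tests
}
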