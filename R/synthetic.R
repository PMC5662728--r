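# Synthetic hierarchical baselines with known truth.
#
# Balding-Nichols construction: ancestral allele frequencies per locus are
# symmetric Dirichlet(1); each reporting group's frequencies are drawn from
# Dirichlet(p_anc (1 - F_between) / F_between), and each population's from
# Dirichlet(p_group (1 - F_within) / F_within), giving nested, F-calibrated
# differentiation (F_ST between groups ~ F_between; between populations of a
# group ~ F_within).  Genotypes are then sampled at Hardy-Weinberg
# equilibrium.

#' Specify a synthetic hierarchical baseline
#'
#' @param n_groups Number of reporting groups.
#' @param pops_per_group Populations per group.
#' @param f_between Differentiation of groups from the ancestral pool, in (0, 1).
#' @param f_within Differentiation of populations from their group, in (0, 1).
#' @param n_loci Number of microsatellite-like loci.
#' @param alleles_per_locus Allele classes per locus (scalar or length
#'   `n_loci` vector, each >= 2).
#' @param n_per_pop Diploid individuals sampled per population.
#' @param missing_rate Probability that a genotype entry is missing, in [0, 1).
#' @param seed RNG seed; the whole baseline is reproducible from it.
#' @return A `baseline_spec` list.
#' @export
baseline_spec <- function(n_groups = 5, pops_per_group = 2, f_between = 0.05,
                          f_within = 0.01, n_loci = 13,
                          alleles_per_locus = 10, n_per_pop = 100,
                          missing_rate = 0, seed = NULL) {
  if (f_between <= 0 || f_between >= 1 || f_within <= 0 || f_within >= 1) {
    abort("differentiation parameters must be in (0, 1).")
  }
  if (any(alleles_per_locus < 2)) abort("`alleles_per_locus` must be >= 2.")
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1).")
  if (n_groups < 1 || pops_per_group < 1 || n_loci < 1 || n_per_pop < 1) {
    abort("counts must be positive.")
  }
  spec <- list(
    n_groups = n_groups, pops_per_group = pops_per_group,
    f_between = f_between, f_within = f_within, n_loci = n_loci,
    alleles_per_locus = rep(alleles_per_locus, length.out = n_loci),
    n_per_pop = n_per_pop, missing_rate = missing_rate, seed = seed
  )
  class(spec) <- "baseline_spec"
  spec
}

#' Generate a synthetic hierarchical baseline
#'
#' @param spec A [baseline_spec()].
#' @return A list: `geno` (genotype tibble), `hierarchy` (tibble
#'   `population`, `group`), `truth_freqs` (tibble `population`, `locus`,
#'   `allele`, `freq` — the true generating frequencies, kept separate from
#'   the sampled data so estimator bias can be separated from sampling
#'   noise), `group_freqs`, and the echoed `spec`.
#' @export
generate_baseline <- function(spec) {
  stopifnot(inherits(spec, "baseline_spec"))
  with_seed_if(spec$seed, {
    loci <- sprintf("Loc%02d", seq_len(spec$n_loci))
    pops <- character(0)
    hier_rows <- list()
    pop_freqs <- list()   # [[locus]] rows = pops
    grp_freqs <- list()
    for (l in seq_len(spec$n_loci)) {
      k <- spec$alleles_per_locus[l]
      p_anc <- as.numeric(rdirichlet(1, rep(1, k)))
      gf <- rdirichlet(spec$n_groups, NULL_guard(p_anc * (1 - spec$f_between) / spec$f_between))
      pf <- matrix(0, spec$n_groups * spec$pops_per_group, k)
      for (g in seq_len(spec$n_groups)) {
        pf[(g - 1) * spec$pops_per_group + seq_len(spec$pops_per_group), ] <-
          rdirichlet(spec$pops_per_group,
                     NULL_guard(gf[g, ] * (1 - spec$f_within) / spec$f_within))
      }
      pop_freqs[[loci[l]]] <- pf
      grp_freqs[[loci[l]]] <- gf
    }
    groups <- sprintf("Group%02d", seq_len(spec$n_groups))
    pops <- as.vector(t(outer(groups, seq_len(spec$pops_per_group),
                              function(g, i) sprintf("%s_Pop%d", g, i))))
    hierarchy <- tibble(
      population = pops,
      group = rep(groups, each = spec$pops_per_group)
    )
    # allele labels: fake fragment sizes, fit 3-digit GENEPOP codes
    labels <- lapply(seq_len(spec$n_loci), function(l) {
      100L + 2L * seq_len(spec$alleles_per_locus[l])
    })
    names(labels) <- loci

    geno_rows <- vector("list", length(pops))
    for (pi in seq_along(pops)) {
      ind_ids <- sprintf("%s_%03d", pops[pi], seq_len(spec$n_per_pop))
      per_locus <- purrr::map(seq_len(spec$n_loci), function(l) {
        p <- pop_freqs[[loci[l]]][pi, ]
        lab <- labels[[loci[l]]]
        a1 <- sample(lab, spec$n_per_pop, replace = TRUE, prob = p)
        a2 <- sample(lab, spec$n_per_pop, replace = TRUE, prob = p)
        tibble(
          collection = pops[pi], indiv = ind_ids, locus = loci[l],
          allele_1 = as.integer(pmin(a1, a2)), allele_2 = as.integer(pmax(a1, a2))
        )
      })
      block <- dplyr::bind_rows(per_locus)
      geno_rows[[pi]] <- dplyr::arrange(
        block, match(.data$indiv, ind_ids), match(.data$locus, loci)
      )
    }
    geno <- dplyr::bind_rows(geno_rows)
    if (spec$missing_rate > 0) {
      geno <- inject_missing(geno, spec$missing_rate, seed = NULL)
    }
    attr(geno, "loci") <- loci

    truth <- purrr::map(loci, function(l) {
      lab <- labels[[l]]
      tibble(
        population = rep(pops, each = length(lab)),
        locus = l,
        allele = rep(lab, times = length(pops)),
        freq = as.vector(t(pop_freqs[[l]]))
      )
    }) %>% dplyr::bind_rows()
    grp_truth <- purrr::map(loci, function(l) {
      lab <- labels[[l]]
      tibble(
        group = rep(groups, each = length(lab)),
        locus = l,
        allele = rep(lab, times = length(groups)),
        freq = as.vector(t(grp_freqs[[l]]))
      )
    }) %>% dplyr::bind_rows()

    list(geno = geno, hierarchy = hierarchy, truth_freqs = truth,
         group_freqs = grp_truth, spec = spec)
  })
}

# rgamma with shape exactly 0 returns 0, which is fine (allele absent), but
# all-zero alpha rows break normalization; nudge zeros to a tiny positive.
NULL_guard <- function(alpha, eps = 1e-12) pmax(alpha, eps)

#' Generate a mixture sample with known origins
#'
#' Pure individuals draw both alleles from their origin population's true
#' frequencies at Hardy-Weinberg equilibrium; F1 admixed individuals draw
#' one allele per locus from each parent population.  The class proportions
#' (pure populations plus F1 pairs) must sum to 1.
#'
#' @param truth_freqs Truth-frequency tibble (`population`, `locus`,
#'   `allele`, `freq`) as produced by [generate_baseline()].
#' @param proportions Named numeric vector: expected fraction of the mixture
#'   drawn pure from each population.
#' @param n Number of mixture individuals.
#' @param f1_pairs Optional tibble `pop_a`, `pop_b`, `rate` of F1 classes;
#'   `sum(proportions) + sum(rate)` must equal 1.
#' @param collection_id Collection id of the mixture.
#' @param seed Optional RNG seed.
#' @return list(`geno` = genotype tibble, `truth` = tibble `indiv`,
#'   `origin` (single population or "popA x popB"), `class`
#'   ("pure" / "f1")).
#' @export
generate_mixture <- function(truth_freqs, proportions, n, f1_pairs = NULL,
                             collection_id = "mixture", seed = NULL) {
  f1_pairs <- f1_pairs %||% tibble(pop_a = character(), pop_b = character(),
                                   rate = numeric())
  tot <- sum(proportions) + sum(f1_pairs$rate)
  if (abs(tot - 1) > 1e-8) abort("class proportions must sum to 1.")
  known <- unique(truth_freqs$population)
  unknown <- setdiff(c(names(proportions), f1_pairs$pop_a, f1_pairs$pop_b), known)
  if (length(unknown)) {
    abort(sprintf("unknown population id(s): %s", paste(unknown, collapse = ", ")))
  }
  loci <- unique(truth_freqs$locus)
  freq_of <- function(pop, l) {
    f <- truth_freqs[truth_freqs$population == pop & truth_freqs$locus == l, ]
    list(allele = f$allele, p = f$freq / sum(f$freq))
  }
  draw <- function(f, m) f$allele[sample.int(length(f$allele), m,
                                             replace = TRUE, prob = f$p)]
  classes <- c(names(proportions),
               sprintf("%s x %s", f1_pairs$pop_a, f1_pairs$pop_b))
  probs <- c(as.numeric(proportions), f1_pairs$rate)
  is_f1 <- c(rep(FALSE, length(proportions)), rep(TRUE, nrow(f1_pairs)))
  with_seed_if(seed, {
    cls <- sample(seq_along(classes), n, replace = TRUE, prob = probs)
    ids <- sprintf("%s_%04d", collection_id, seq_len(n))
    rows <- vector("list", length(loci))
    for (li in seq_along(loci)) {
      l <- loci[li]
      a1 <- integer(n)
      a2 <- integer(n)
      for (ci in unique(cls)) {
        sel <- which(cls == ci)
        if (is_f1[ci]) {
          pa <- f1_pairs$pop_a[ci - length(proportions)]
          pb <- f1_pairs$pop_b[ci - length(proportions)]
          fa <- freq_of(pa, l)
          fb <- freq_of(pb, l)
          a1[sel] <- draw(fa, length(sel))
          a2[sel] <- draw(fb, length(sel))
        } else {
          f <- freq_of(classes[ci], l)
          a1[sel] <- draw(f, length(sel))
          a2[sel] <- draw(f, length(sel))
        }
      }
      rows[[li]] <- tibble(
        collection = collection_id, indiv = ids, locus = l,
        allele_1 = as.integer(pmin(a1, a2)), allele_2 = as.integer(pmax(a1, a2))
      )
    }
    geno <- dplyr::bind_rows(rows)
    geno <- dplyr::arrange(geno, match(.data$indiv, ids), match(.data$locus, loci))
    truth <- tibble(
      indiv = ids,
      origin = classes[cls],
      class = ifelse(is_f1[cls], "f1", "pure")
    )
    list(geno = geno, truth = truth)
  })
}

#' Randomly set genotype entries to missing
#'
#' Each individual-by-locus entry is independently set missing with the
#' given rate (both alleles at once, preserving the all-or-nothing missing
#' convention).
#'
#' @param geno Genotype tibble.
#' @param rate Missing probability in [0, 1).
#' @param seed Optional RNG seed.
#' @return The genotype tibble with injected missingness.
#' @export
inject_missing <- function(geno, rate, seed = NULL) {
  check_genotypes(geno)
  if (rate < 0 || rate >= 1) abort("`rate` must be in [0, 1).")
  if (rate == 0) return(geno)
  with_seed_if(seed, {
    hit <- runif(nrow(geno)) < rate
    geno$allele_1[hit] <- NA_integer_
    geno$allele_2[hit] <- NA_integer_
    geno
  })
}

#' Generate a sister-structured founding-simulation scenario
#'
#' Builds a baseline emulating the structure that makes admixture-induced
#' misassignment visible: two truth reporting groups, each with one closely
#' related sister group (low pairwise divergence, on the order of the
#' within-lineage splits of a real coast-wide baseline), plus a large number
#' of unrelated reporting groups at substantially higher divergence.  It is
#' produced by drawing pairs of populations inside Balding-Nichols groups
#' and then promoting every population to its own reporting group, so that
#' former group-mates become sister groups.
#'
#' @param n_unrelated Number of unrelated reporting groups (default 40).
#' @param f_between Divergence of lineage clusters from the ancestral pool
#'   (default 0.07).
#' @param f_sister Divergence of sister populations from their shared
#'   lineage frequency (default 0.0075; pairwise sister theta is roughly
#'   twice this).
#' @param n_loci,alleles_per_locus,n_per_pop Baseline dimensions (defaults
#'   12 loci, 14 alleles, 50 diploids).
#' @param seed RNG seed.
#' @return list(`geno`, `hierarchy` (one reporting group per population),
#'   `sisters` (symmetric pairs for the two truth groups), `source_a`,
#'   `source_b` (the two truth populations), `truth_freqs`, `spec`).
#' @export
generate_sister_scenario <- function(n_unrelated = 40, f_between = 0.07,
                                     f_sister = 0.0075, n_loci = 12,
                                     alleles_per_locus = 14, n_per_pop = 50,
                                     seed = NULL) {
  n_clusters <- 2L + ceiling(n_unrelated / 2)
  base <- generate_baseline(baseline_spec(
    n_groups = n_clusters, pops_per_group = 2, f_between = f_between,
    f_within = f_sister, n_loci = n_loci,
    alleles_per_locus = alleles_per_locus, n_per_pop = n_per_pop, seed = seed
  ))
  # promote each population to its own reporting group
  hierarchy <- tibble(population = base$hierarchy$population,
                      group = base$hierarchy$population)
  pops_of <- function(g) base$hierarchy$population[base$hierarchy$group == g]
  c1 <- pops_of("Group01")
  c2 <- pops_of("Group02")
  sisters <- tibble(
    group = c(c1, c2),
    sister = c(rev(c1), rev(c2))
  )
  list(geno = base$geno, hierarchy = hierarchy, sisters = sisters,
       source_a = c1[1], source_b = c2[1],
       truth_freqs = base$truth_freqs, spec = base$spec)
}
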