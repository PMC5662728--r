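# Rannala-Mountain conditional-likelihood individual assignment.
#
# The per-locus genotype probability is the Dirichlet-multinomial posterior
# predictive under a symmetric Dirichlet(1/k) prior on the k allele classes
# of the locus, conditioning on the baseline allele counts n_a (n gene
# copies total):
#   homozygote aa:    (n_a + 1/k)(n_a + 1 + 1/k) / ((n + 1)(n + 2))
#   heterozygote ab:  2 (n_a + 1/k)(n_b + 1/k)   / ((n + 1)(n + 2))
# Missing loci are skipped (factor 1); loci multiply in log space.

#' Rannala-Mountain genotype probability at one locus
#'
#' @param genotype Integer vector of two allele indices (1-based positions in
#'   the locus's allele registry), or `NA` for a missing genotype.
#' @param counts Non-negative baseline allele counts for the population at
#'   this locus (length k).
#' @param k Number of allele classes in the prior; defaults to
#'   `length(counts)`.
#' @param leave_out If TRUE, the individual's own two alleles are removed
#'   from `counts` before evaluation (leave-one-out); errors if the counts do
#'   not contain them.
#' @return The genotype probability (a single number; 1 for a missing
#'   genotype).
#' @export
rm_genotype_probability <- function(genotype, counts, k = length(counts),
                                    leave_out = FALSE) {
  if (k < 1) abort("`k` must be at least 1.")
  if (any(counts < 0)) abort("`counts` must be non-negative.")
  if (all(is.na(genotype))) return(1)
  a <- genotype[1]
  b <- genotype[2]
  if (leave_out) {
    counts[a] <- counts[a] - 1
    counts[b] <- counts[b] - 1
    if (any(counts < 0)) {
      abort("leave-one-out requested for alleles not present in the stated counts.")
    }
  }
  n <- sum(counts)
  denom <- (n + 1) * (n + 2)
  if (a == b) {
    (counts[a] + 1 / k) * (counts[a] + 1 + 1 / k) / denom
  } else {
    2 * (counts[a] + 1 / k) * (counts[b] + 1 / k) / denom
  }
}

# Log-likelihood matrix (individuals x populations) for a set of query calls
# against per-population baseline counts.  `calls` and `counts` are the
# per-locus structures from geno_matrices()/count_matrices().
# Returns list(ll = n x P matrix, n_loci = scored loci per individual).
rm_loglik_matrix <- function(calls, counts, loci) {
  n_ind <- nrow(calls[[loci[1]]])
  n_pop <- nrow(counts[[loci[1]]])
  ll <- matrix(0, n_ind, n_pop, dimnames = list(NULL, rownames(counts[[loci[1]]])))
  n_loci <- integer(n_ind)
  for (l in loci) {
    cm <- calls[[l]]
    C <- counts[[l]]
    k <- ncol(C)
    alpha <- C + 1 / k
    ntot <- rowSums(C)
    log_denom <- log(ntot + 1) + log(ntot + 2)
    ok <- which(!is.na(cm[, 1]))
    if (!length(ok)) next
    a <- cm[ok, 1]
    b <- cm[ok, 2]
    hom <- a == b
    # columns of t(alpha)[a, ] etc: P x m slices via matrix indexing
    la <- log(alpha)[, a, drop = FALSE]          # P x m
    lb_part <- log(alpha[, b, drop = FALSE] + outer(rep(1, nrow(C)), as.numeric(hom)))
    contrib <- la + lb_part +
      matrix(log(2) * as.numeric(!hom), nrow(C), length(ok), byrow = TRUE) -
      matrix(log_denom, nrow(C), length(ok))
    ll[ok, ] <- ll[ok, ] + t(contrib)
    n_loci[ok] <- n_loci[ok] + 1L
  }
  list(ll = ll, n_loci = n_loci)
}

#' Individual assignment posteriors against a baseline
#'
#' Computes, for every query individual, the posterior probability of
#' membership in each baseline population under equal population priors:
#' `q_ij = L_ij / sum_j' L_ij'` with the Rannala-Mountain conditional
#' likelihood `L`.  The allele-class count `k` per locus is the number of
#' distinct alleles in the union registry of baseline and queries, constant
#' across populations, so query alleles unseen in a reference population
#' still carry prior mass.
#'
#' With `leave_one_out = TRUE` the queries must be baseline members (matched
#' by collection and individual id); each individual's own two alleles are
#' removed from its home population's counts before its likelihood there is
#' evaluated — the jackknife used for self-assignment.
#'
#' @param mixture Genotype tibble of query individuals.
#' @param baseline Genotype tibble of reference collections.
#' @param leave_one_out Jackknife the home-population counts (see above).
#' @return A `gsi_posterior` tibble in long format: `collection`, `indiv`,
#'   `unit` (baseline population), `posterior`, `n_loci`, `unassignable`
#'   (zero scored loci; posterior NA), `tie` (maximum attained by several
#'   units).  Attribute `"level"` is `"population"`.
#' @export
assignment_posteriors <- function(mixture, baseline, leave_one_out = FALSE) {
  check_genotypes(mixture, "mixture")
  check_genotypes(baseline, "baseline")
  pops <- unique(baseline$collection)
  if (!length(pops)) abort("baseline is empty.")
  registry <- locus_registry(baseline, mixture)
  reg <- registry_list(registry)
  loci <- intersect(locus_order(baseline), names(reg))
  counts <- count_matrices(baseline, reg, pops = pops, loci = loci)
  gm <- geno_matrices(mixture, reg, loci)
  res <- rm_loglik_matrix(gm$calls, counts, loci)
  ll <- res$ll

  if (leave_one_out) {
    home <- match(gm$ind$collection, pops)
    if (anyNA(home)) {
      abort("leave_one_out requires every query to belong to a baseline population.")
    }
    base_gm <- geno_matrices(baseline, reg, loci)
    base_key <- paste(base_gm$ind$collection, base_gm$ind$indiv, sep = "\r")
    q_key <- paste(gm$ind$collection, gm$ind$indiv, sep = "\r")
    if (anyNA(match(q_key, base_key))) {
      abort("leave_one_out requires every query individual to be present in the baseline.")
    }
    for (l in loci) {
      cm <- gm$calls[[l]]
      C <- counts[[l]]
      k <- ncol(C)
      ok <- which(!is.na(cm[, 1]))
      for (i in ok) {
        j <- home[i]
        g <- cm[i, ]
        full <- rm_genotype_probability(g, C[j, ], k = k)
        loo <- rm_genotype_probability(g, C[j, ], k = k, leave_out = TRUE)
        ll[i, j] <- ll[i, j] - log(full) + log(loo)
      }
    }
  }

  norm <- row_logsumexp(ll)
  q <- exp(ll - norm)
  unassignable <- res$n_loci == 0L
  q[unassignable, ] <- NA_real_
  max_q <- apply(q, 1L, function(x) if (all(is.na(x))) NA_real_ else max(x))
  tie <- vapply(seq_len(nrow(q)), function(i) {
    if (is.na(max_q[i])) return(FALSE)
    sum(abs(q[i, ] - max_q[i]) < 1e-9) > 1L
  }, logical(1))

  out <- tibble(
    collection = rep(gm$ind$collection, times = length(pops)),
    indiv = rep(gm$ind$indiv, times = length(pops)),
    unit = rep(pops, each = nrow(gm$ind)),
    posterior = as.vector(q),
    n_loci = rep(res$n_loci, times = length(pops)),
    unassignable = rep(unassignable, times = length(pops)),
    tie = rep(tie, times = length(pops))
  )
  class(out) <- c("gsi_posterior", class(out))
  attr(out, "level") <- "population"
  out
}

#' Aggregate population posteriors to reporting groups
#'
#' Group membership probability is the sum of member-population
#' probabilities; rows still sum to one.
#'
#' @param posteriors A `gsi_posterior` tibble at population level.
#' @param hierarchy Hierarchy tibble (`population`, `group`) covering every
#'   baseline population present.
#' @return A `gsi_posterior` tibble with `unit` = reporting group and
#'   attribute `"level" = "group"`.
#' @export
aggregate_to_groups <- function(posteriors, hierarchy) {
  unmapped <- setdiff(unique(posteriors$unit), hierarchy$population)
  if (length(unmapped)) {
    abort(sprintf("population(s) not mapped to a group: %s",
                  paste(unmapped, collapse = ", ")))
  }
  grp <- hierarchy$group[match(posteriors$unit, hierarchy$population)]
  out <- posteriors %>%
    mutate(unit = grp) %>%
    dplyr::group_by(.data$collection, .data$indiv, .data$unit) %>%
    dplyr::summarise(
      posterior = sum(.data$posterior),
      n_loci = .data$n_loci[1],
      unassignable = .data$unassignable[1],
      .groups = "drop"
    )
  # recompute ties at group level
  out <- out %>%
    dplyr::group_by(.data$collection, .data$indiv) %>%
    mutate(tie = !all(is.na(.data$posterior)) &
             sum(abs(.data$posterior - max(.data$posterior)) < 1e-9) > 1L) %>%
    dplyr::ungroup()
  class(out) <- c("gsi_posterior", class(out))
  attr(out, "level") <- "group"
  out
}

#' Maximum a posteriori assignment per individual
#'
#' Ties are broken to the first unit in baseline order and flagged.
#'
#' @param posteriors A `gsi_posterior` tibble.
#' @return One row per individual: `collection`, `indiv`, `unit`,
#'   `posterior`, `n_loci`, `tie`, `unassignable`.
#' @export
map_assignments <- function(posteriors) {
  units <- unique(posteriors$unit)
  posteriors %>%
    dplyr::group_by(.data$collection, .data$indiv) %>%
    dplyr::summarise(
      unit = if (all(is.na(.data$posterior))) NA_character_ else
        .data$unit[order(match(.data$unit, units))][
          which.max(.data$posterior[order(match(.data$unit, units))])],
      posterior = if (all(is.na(.data$posterior))) NA_real_ else
        max(.data$posterior),
      n_loci = .data$n_loci[1],
      tie = .data$tie[1],
      unassignable = .data$unassignable[1],
      .groups = "drop"
    )
}

#' Leave-one-out self-assignment confusion matrix
#'
#' Every baseline individual is assigned with its own alleles removed from
#' its home population's counts; assignments are tabulated against the true
#' population (or reporting group).
#'
#' @param baseline Baseline genotype tibble.
#' @param hierarchy Hierarchy tibble; required for `level = "group"`.
#' @param level `"population"` or `"group"`.
#' @return A `gsi_confusion` tibble: `true_unit`, `assigned_unit`, `n`,
#'   `rate` (row-normalized).  `glance()` gives overall accuracy.
#' @export
self_assignment_confusion <- function(baseline, hierarchy = NULL,
                                      level = c("population", "group")) {
  level <- match.arg(level)
  post <- assignment_posteriors(baseline, baseline, leave_one_out = TRUE)
  truth <- dplyr::distinct(baseline[, c("collection", "indiv")])
  if (level == "group") {
    if (is.null(hierarchy)) abort("`hierarchy` is required at group level.")
    post <- aggregate_to_groups(post, hierarchy)
    truth$true_unit <- hierarchy$group[match(truth$collection, hierarchy$population)]
  } else {
    truth$true_unit <- truth$collection
  }
  mapped <- map_assignments(post)
  mapped <- dplyr::left_join(mapped, truth, by = c("collection", "indiv"))
  mapped <- dplyr::rename(mapped, assigned_unit = "unit")
  out <- mapped %>%
    dplyr::count(.data$true_unit, .data$assigned_unit, name = "n") %>%
    dplyr::group_by(.data$true_unit) %>%
    mutate(rate = .data$n / sum(.data$n)) %>%
    dplyr::ungroup()
  class(out) <- c("gsi_confusion", class(out))
  attr(out, "level") <- level
  out
}

#' @export
glance.gsi_confusion <- function(x, ...) {
  correct <- sum(x$n[x$true_unit == x$assigned_unit])
  tibble(accuracy = correct / sum(x$n), n = sum(x$n),
         level = attr(x, "level"))
}
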