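# Mixed-origin founding simulation: build an ideal admixed population with
# allele frequencies intermediate between two baseline sources, draw
# genotypes at Hardy-Weinberg equilibrium, assign them against the full
# baseline, and tabulate where they land relative to the truth.

#' Intermediate allele frequencies of an admixed founding population
#'
#' The admixed population founded by large and equal numbers of individuals
#' from two sources has, at equilibrium, allele frequencies equal to the
#' arithmetic mean of the two sources' maximum-likelihood frequency
#' estimates (set `pooled = TRUE` to average counts instead — equivalent
#' only when the sources were scored equally).
#'
#' @param geno Baseline genotype tibble containing both sources.
#' @param source_a,source_b Source collection ids.
#' @param pooled Average pooled counts rather than estimated frequencies.
#' @return Tibble `locus`, `allele`, `freq` (frequencies sum to 1 within
#'   locus).  Loci unscored in either source are dropped with a warning.
#' @export
build_admixed_frequencies <- function(geno, source_a, source_b, pooled = FALSE) {
  check_genotypes(geno)
  sub <- geno[geno$collection %in% c(source_a, source_b), ]
  if (length(unique(sub$collection)) < 2L) {
    abort("both source populations must be present in the baseline.")
  }
  fr <- allele_counts(sub)
  wide <- tidyr::pivot_wider(fr, id_cols = c("locus", "allele"),
                             names_from = "collection",
                             values_from = c("count", "total", "freq"))
  ca <- wide[[paste0("count_", source_a)]]
  cb <- wide[[paste0("count_", source_b)]]
  ta <- wide[[paste0("total_", source_a)]]
  tb <- wide[[paste0("total_", source_b)]]
  bad_loci <- unique(wide$locus[is.na(ta) | is.na(tb) | ta == 0 | tb == 0])
  if (length(bad_loci)) {
    warn(sprintf("dropping locus/loci unscored in a source: %s",
                 paste(bad_loci, collapse = ", ")))
    keep <- !(wide$locus %in% bad_loci)
    wide <- wide[keep, ]
    ca <- ca[keep]; cb <- cb[keep]; ta <- ta[keep]; tb <- tb[keep]
  }
  if (!nrow(wide)) abort("sources share no scored loci.")
  freq <- if (pooled) (ca + cb) / (ta + tb) else (ca / ta + cb / tb) / 2
  tibble(locus = wide$locus, allele = wide$allele, freq = freq) %>%
    dplyr::filter(.data$freq > 0) %>%
    dplyr::arrange(.data$locus, .data$allele)
}

#' Sample diploid genotypes at Hardy-Weinberg equilibrium
#'
#' Each individual draws two alleles independently per locus from the given
#' frequencies; loci are independent.
#'
#' @param freqs Tibble `locus`, `allele`, `freq` (summing to 1 per locus).
#' @param n Number of individuals (>= 1).
#' @param collection_id Id for the resulting collection.
#' @param seed Optional RNG seed.
#' @return A genotype tibble.
#' @export
sample_hwe_genotypes <- function(freqs, n, collection_id = "simulated",
                                 seed = NULL) {
  if (n < 1) abort("`n` must be at least 1.")
  loci <- unique(freqs$locus)
  with_seed_if(seed, {
    rows <- purrr::map(loci, function(l) {
      f <- freqs[freqs$locus == l, ]
      p <- f$freq / sum(f$freq)
      a1 <- f$allele[sample.int(nrow(f), n, replace = TRUE, prob = p)]
      a2 <- f$allele[sample.int(nrow(f), n, replace = TRUE, prob = p)]
      tibble(
        collection = collection_id,
        indiv = sprintf("%s_%04d", collection_id, seq_len(n)),
        locus = l,
        allele_1 = as.integer(pmin(a1, a2)),
        allele_2 = as.integer(pmax(a1, a2))
      )
    })
    out <- dplyr::bind_rows(rows)
    dplyr::arrange(out, match(.data$indiv, unique(.data$indiv)),
                   match(.data$locus, loci))
  })
}

#' Categorize assignments of simulated fish as true / sister / unrelated
#'
#' Each fish is categorized by its maximum-a-posteriori reporting group:
#' a truth group (either source's group) counts as `true`, a declared sister
#' of a truth group as `sister`, anything else as `unrelated`.  The
#' high-confidence share is computed among unrelated-assigned fish only:
#' the fraction whose maximum posterior reaches `p_threshold`.
#'
#' @param group_posteriors A group-level `gsi_posterior` tibble for the
#'   simulated fish.
#' @param truth_groups Character vector of the sources' reporting groups.
#' @param sisters Sister-pair tibble (`group`, `sister`), e.g. from
#'   [sister_pairs()]; may be empty.
#' @param p_threshold High-confidence posterior cutoff (default 0.8).
#' @return A `founding_report` list: `fractions` (true/sister/unrelated,
#'   summing to 1), `fraction_unrelated_highconf`, `per_group` counts,
#'   `n`, `p_threshold`, `truth_groups`, `sister_groups`.
#' @export
categorize_assignments <- function(group_posteriors, truth_groups, sisters,
                                   p_threshold = 0.8) {
  if (p_threshold <= 0 || p_threshold >= 1) abort("`p_threshold` must be in (0, 1).")
  groups <- unique(group_posteriors$unit)
  missing <- setdiff(truth_groups, groups)
  if (length(missing)) {
    abort(sprintf("truth group(s) absent from hierarchy: %s",
                  paste(missing, collapse = ", ")))
  }
  sister_groups <- setdiff(
    unique(sisters$sister[sisters$group %in% truth_groups]),
    truth_groups
  )
  mapped <- map_assignments(group_posteriors)
  mapped <- mapped[!mapped$unassignable, ]
  n <- nrow(mapped)
  category <- ifelse(mapped$unit %in% truth_groups, "true",
                     ifelse(mapped$unit %in% sister_groups, "sister", "unrelated"))
  fractions <- c(
    true = sum(category == "true") / n,
    sister = sum(category == "sister") / n,
    unrelated = sum(category == "unrelated") / n
  )
  unrel <- category == "unrelated"
  highconf <- if (any(unrel)) {
    sum(mapped$posterior[unrel] >= p_threshold) / sum(unrel)
  } else NA_real_
  per_group <- mapped %>%
    dplyr::count(.data$unit, name = "n") %>%
    mutate(category = ifelse(.data$unit %in% truth_groups, "true",
                             ifelse(.data$unit %in% sister_groups, "sister",
                                    "unrelated"))) %>%
    dplyr::arrange(dplyr::desc(.data$n))
  out <- list(
    fractions = fractions,
    fraction_unrelated_highconf = highconf,
    per_group = per_group,
    n = n,
    p_threshold = p_threshold,
    truth_groups = truth_groups,
    sister_groups = sister_groups
  )
  class(out) <- "founding_report"
  out
}

#' Run the mixed-origin founding simulation
#'
#' Pipeline: intermediate admixed frequencies from the two sources ->
#' Hardy-Weinberg genotype sample of `n` fish -> assignment against the full
#' baseline -> aggregation to reporting groups -> true/sister/unrelated
#' tabulation.  Pure-origin control cohorts of the same size, drawn from
#' each source's own estimated frequencies, are always simulated alongside
#' to benchmark the baseline's ordinary misassignment level.
#'
#' @param baseline Baseline genotype tibble.
#' @param hierarchy Hierarchy tibble (`population`, `group`).
#' @param source_a,source_b Source population ids (distinct).
#' @param sisters Sister-pair tibble (`group`, `sister`); default empty.
#' @param n Number of simulated admixed fish (default 1000).
#' @param p_threshold High-confidence posterior cutoff (default 0.8).
#' @param seed Optional RNG seed; the full report is reproducible given it.
#' @return A `founding_report` with the admixed tabulation plus
#'   `pure_controls` (a per-source list of `founding_report`s) and a `spec`
#'   echo.  `glance()` gives the one-row summary.
#' @export
run_founding_simulation <- function(baseline, hierarchy, source_a, source_b,
                                    sisters = NULL, n = 1000,
                                    p_threshold = 0.8, seed = NULL) {
  check_genotypes(baseline)
  if (source_a == source_b) abort("sources must be distinct populations.")
  pops <- unique(baseline$collection)
  missing <- setdiff(c(source_a, source_b), pops)
  if (length(missing)) {
    abort(sprintf("source(s) not in baseline: %s", paste(missing, collapse = ", ")))
  }
  validate_baseline(baseline, hierarchy)
  sisters <- sisters %||% tibble(group = character(), sister = character())
  truth_groups <- unique(hierarchy$group[match(c(source_a, source_b),
                                               hierarchy$population)])

  run_cohort <- function(freqs, id, cohort_seed) {
    fish <- sample_hwe_genotypes(freqs, n, collection_id = id, seed = cohort_seed)
    post <- assignment_posteriors(fish, baseline)
    gpost <- aggregate_to_groups(post, hierarchy)
    categorize_assignments(gpost, truth_groups, sisters, p_threshold)
  }

  adm_freq <- build_admixed_frequencies(baseline, source_a, source_b)
  fr <- allele_counts(baseline[baseline$collection %in% c(source_a, source_b), ])
  pure_freq <- function(src) {
    f <- fr[fr$collection == src & fr$count > 0, c("locus", "allele", "freq")]
    f[f$locus %in% unique(adm_freq$locus), ]
  }
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else
    lapply(1:3, function(i) substream(seed, i))
  report <- run_cohort(adm_freq, "admixed", seeds[[1]])
  report$pure_controls <- list(
    run_cohort(pure_freq(source_a), paste0("pure_", source_a), seeds[[2]]),
    run_cohort(pure_freq(source_b), paste0("pure_", source_b), seeds[[3]])
  )
  names(report$pure_controls) <- c(source_a, source_b)
  report$spec <- list(source_a = source_a, source_b = source_b, n = n,
                      p_threshold = p_threshold, seed = seed)
  report
}

#' @export
print.founding_report <- function(x, ...) {
  cat("Mixed-origin founding simulation:", x$n, "fish\n")
  cat(sprintf("  assigned to true groups:      %5.1f%%\n", 100 * x$fractions["true"]))
  cat(sprintf("  assigned to sister groups:    %5.1f%%\n", 100 * x$fractions["sister"]))
  cat(sprintf("  assigned to unrelated groups: %5.1f%%\n", 100 * x$fractions["unrelated"]))
  if (!is.na(x$fraction_unrelated_highconf)) {
    cat(sprintf("  of unrelated, P >= %.1f:       %5.1f%%\n",
                x$p_threshold, 100 * x$fraction_unrelated_highconf))
  }
  invisible(x)
}

#' @export
tidy.founding_report <- function(x, ...) x$per_group

#' @export
glance.founding_report <- function(x, ...) {
  tibble(
    fraction_true = x$fractions[["true"]],
    fraction_sister = x$fractions[["sister"]],
    fraction_unrelated = x$fractions[["unrelated"]],
    fraction_unrelated_highconf = x$fraction_unrelated_highconf,
    n = x$n,
    p_threshold = x$p_threshold
  )
}

#' Bar plot of founding-simulation assignment categories
#'
#' @param object A `founding_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.founding_report <- function(object, ...) {
  df <- tibble(category = factor(names(object$fractions),
                                 levels = c("true", "sister", "unrelated")),
               fraction = as.numeric(object$fractions))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$fraction,
                                   fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(y = "fraction of simulated fish", x = NULL) +
    ggplot2::theme_minimal()
}
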