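test_that("Rannala-Mountain genotype probabilities match hand evaluations", {
  # counts A:9 B:1 (n = 10), k = 2
  expect_equal(rm_genotype_probability(c(1, 2), c(9, 1), k = 2),
               2 * 9.5 * 1.5 / 132, tolerance = 1e-12)
  expect_equal(rm_genotype_probability(c(1, 1), c(9, 1), k = 2),
               9.5 * 10.5 / 132, tolerance = 1e-12)
  # prior-only population with zero counts
  expect_equal(rm_genotype_probability(c(1, 1), c(0, 0), k = 2),
               0.5 * 1.5 / 2, tolerance = 1e-12)
  # missing genotype contributes a unit factor
  expect_equal(rm_genotype_probability(c(NA, NA), c(3, 2), k = 2), 1)
})

test_that("RM probability equals the Polya-urn enumeration oracle on a count grid", {
  for (k in 2:3) {
    grid <- expand.grid(rep(list(0:6), k))
    # thin the grid to keep the unit test quick; the acceptance test runs full
    grid <- grid[seq(1, nrow(grid), by = 3), , drop = FALSE]
    for (i in seq_len(nrow(grid))) {
      counts <- as.numeric(grid[i, ])
      for (a in 1:k) for (b in a:k) {
        expect_equal(
          rm_genotype_probability(c(a, b), counts, k = k),
          rm_urn_oracle(c(a, b), counts, k = k),
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("leave-one-out errors when the stated counts cannot contain the alleles", {
  expect_error(rm_genotype_probability(c(1, 1), c(1, 5), k = 2, leave_out = TRUE),
               "leave-one-out")
})

test_that("posteriors are symmetric for identical baselines and match the hand case", {
  base <- dplyr::bind_rows(
    toy_geno("pop1", L1 = list(c(1, 1), c(1, 2), c(1, 1))),
    toy_geno("pop2", L1 = list(c(1, 1), c(1, 2), c(1, 1)))
  )
  q <- toy_geno("mix", L1 = list(c(1, 1), c(1, 2)))
  p <- assignment_posteriors(q, base)
  expect_equal(p$posterior, rep(0.5, 4), tolerance = 1e-12)
  expect_true(all(p$tie))

  # pop1 A:9 B:1, pop2 A:1 B:9 at one locus, query AA
  base2 <- dplyr::bind_rows(
    toy_geno("pop1", L1 = c(replicate(4, c(1, 1), simplify = FALSE),
                            list(c(1, 2)))),
    toy_geno("pop2", L1 = c(replicate(4, c(2, 2), simplify = FALSE),
                            list(c(1, 2))))
  )
  q2 <- toy_geno("mix", L1 = list(c(1, 1)))
  p2 <- assignment_posteriors(q2, base2)
  expect_equal(p2$posterior[p2$unit == "pop1"], 99.75 / 103.5, tolerance = 1e-9)
})

test_that("posterior rows sum to one and zero-locus individuals are flagged", {
  b <- generate_baseline(baseline_spec(
    n_groups = 3, pops_per_group = 2, f_between = 0.05, f_within = 0.01,
    n_loci = 6, alleles_per_locus = 6, n_per_pop = 20, seed = 31
  ))
  mix <- generate_mixture(
    b$truth_freqs,
    setNames(c(0.5, 0.5), unique(b$hierarchy$population)[1:2]),
    30, seed = 32
  )
  geno <- mix$geno
  # blank out one individual entirely
  victim <- unique(geno$indiv)[1]
  geno$allele_1[geno$indiv == victim] <- NA_integer_
  geno$allele_2[geno$indiv == victim] <- NA_integer_
  p <- assignment_posteriors(geno, b$geno)
  sums <- p %>%
    dplyr::filter(!.data$unassignable) %>%
    dplyr::group_by(.data$indiv) %>%
    dplyr::summarise(s = sum(.data$posterior))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_true(all(p$unassignable[p$indiv == victim]))
  expect_true(all(is.na(p$posterior[p$indiv == victim])))
})

test_that("leave-one-out equals removing the individual and reassigning", {
  b <- generate_baseline(baseline_spec(
    n_groups = 2, pops_per_group = 2, f_between = 0.05, f_within = 0.01,
    n_loci = 5, alleles_per_locus = 6, n_per_pop = 15, seed = 55
  ))
  geno <- b$geno
  loo <- assignment_posteriors(geno, geno, leave_one_out = TRUE)
  picks <- withr::with_seed(56, sample(unique(geno$indiv), 8))
  for (id in picks) {
    fish <- geno[geno$indiv == id, ]
    rest <- geno[geno$indiv != id, ]
    manual <- assignment_posteriors(fish, rest)
    got <- loo[loo$indiv == id, ]
    expect_equal(
      got$posterior[match(manual$unit, got$unit)],
      manual$posterior,
      tolerance = 1e-12
    )
  }
})

test_that("group aggregation conserves row sums and sums member populations", {
  b <- generate_baseline(baseline_spec(
    n_groups = 3, pops_per_group = 2, f_between = 0.05, f_within = 0.01,
    n_loci = 5, alleles_per_locus = 6, n_per_pop = 15, seed = 61
  ))
  mix <- generate_mixture(
    b$truth_freqs,
    setNames(1, b$hierarchy$population[1]), 10, seed = 62
  )
  p <- assignment_posteriors(mix$geno, b$geno)
  gp <- aggregate_to_groups(p, b$hierarchy)
  expect_equal(sort(unique(gp$unit)), sort(unique(b$hierarchy$group)))
  sums <- gp %>% dplyr::group_by(.data$indiv) %>%
    dplyr::summarise(s = sum(.data$posterior))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  # direct sum check for one individual / group
  id <- unique(p$indiv)[1]
  g1pops <- b$hierarchy$population[b$hierarchy$group == "Group01"]
  expect_equal(
    gp$posterior[gp$indiv == id & gp$unit == "Group01"],
    sum(p$posterior[p$indiv == id & p$unit %in% g1pops]),
    tolerance = 1e-12
  )
  expect_error(aggregate_to_groups(p, b$hierarchy[-1, ]), "not mapped")
})

test_that("self-assignment separates divergent populations and not identical ones", {
  div <- dplyr::bind_rows(
    toy_geno("P1", L1 = replicate(50, c(1, 1), simplify = FALSE),
             L2 = replicate(50, c(3, 3), simplify = FALSE)),
    toy_geno("P2", L1 = replicate(50, c(2, 2), simplify = FALSE),
             L2 = replicate(50, c(4, 4), simplify = FALSE))
  )
  cm <- self_assignment_confusion(div)
  expect_gte(glance(cm)$accuracy, 0.98)

  # two iid samples from (near-)identical frequency distributions
  b <- generate_baseline(baseline_spec(
    n_groups = 2, pops_per_group = 1, f_between = 1e-4, f_within = 1e-4,
    n_loci = 8, alleles_per_locus = 6, n_per_pop = 40, seed = 71
  ))
  cm2 <- self_assignment_confusion(b$geno)
  acc <- glance(cm2)$accuracy
  expect_gt(acc, 0.3)
  expect_lt(acc, 0.7)
})

test_that("self-assignment accuracy grows with baseline divergence", {
  acc_at <- function(f) {
    mean(vapply(1:3, function(s) {
      b <- generate_baseline(baseline_spec(
        n_groups = 3, pops_per_group = 1, f_between = f, f_within = 1e-4,
        n_loci = 8, alleles_per_locus = 8, n_per_pop = 30, seed = 400 + s
      ))
      glance(self_assignment_confusion(b$geno))$accuracy
    }, numeric(1)))
  }
  accs <- vapply(c(0.01, 0.05, 0.2), acc_at, numeric(1))
  expect_true(all(diff(accs) > 0))
})

test_that("mean-posterior mixture averages rows and EM matches empirical fractions when degenerate", {
  post <- tibble::tibble(
    collection = "mix",
    indiv = rep(c("i1", "i2"), each = 2),
    unit = rep(c("u1", "u2"), times = 2),
    posterior = c(1, 0, 0.5, 0.5),
    n_loci = 5L, unassignable = FALSE, tie = FALSE
  )
  class(post) <- c("gsi_posterior", class(post))
  est <- estimate_mixture(post, method = "mean-posterior")
  expect_equal(est$pi, c(0.75, 0.25))
  expect_equal(sum(est$n_map), 2L)

  # fully divergent baseline: EM equals the empirical fraction per source
  div <- dplyr::bind_rows(
    toy_geno("P1", L1 = replicate(30, c(1, 1), simplify = FALSE)),
    toy_geno("P2", L1 = replicate(30, c(2, 2), simplify = FALSE))
  )
  mixg <- dplyr::bind_rows(
    toy_geno("m1", L1 = replicate(18, c(1, 1), simplify = FALSE)),
    toy_geno("m2", L1 = replicate(12, c(2, 2), simplify = FALSE))
  )
  mixg$collection <- "mix"
  p <- assignment_posteriors(mixg, div)
  em <- estimate_mixture(p, method = "em")
  expect_equal(sort(em$pi), c(0.4, 0.6), tolerance = 1e-3)
})

test_that("EM log-likelihood is monotone and the fixed point is self-consistent", {
  b <- generate_baseline(baseline_spec(
    n_groups = 2, pops_per_group = 1, f_between = 0.05, f_within = 1e-4,
    n_loci = 10, alleles_per_locus = 8, n_per_pop = 100, seed = 91
  ))
  pops <- unique(b$hierarchy$population)
  mix <- generate_mixture(b$truth_freqs, setNames(c(0.6, 0.4), pops), 100,
                          seed = 92)
  p <- assignment_posteriors(mix$geno, b$geno)
  em <- estimate_mixture(p, method = "em", tol = 1e-8)
  ll <- attr(em, "log_lik")
  expect_true(all(diff(ll) >= -1e-9))
  expect_true(attr(em, "converged"))
  # self-consistency: pi = mean responsibility under pi
  wide <- tidyr::pivot_wider(p[, c("indiv", "unit", "posterior")],
                             names_from = "unit", values_from = "posterior")
  q <- as.matrix(wide[, em$unit])
  num <- sweep(q, 2, em$pi, "*")
  expect_equal(colMeans(num / rowSums(num)), setNames(em$pi, em$unit),
               tolerance = 1e-6)
})

test_that("mean-posterior and EM agree on near-degenerate posteriors", {
  b <- generate_baseline(baseline_spec(
    n_groups = 3, pops_per_group = 1, f_between = 0.35, f_within = 1e-4,
    n_loci = 12, alleles_per_locus = 8, n_per_pop = 60, seed = 95
  ))
  pops <- unique(b$hierarchy$population)
  mix <- generate_mixture(b$truth_freqs, setNames(c(0.5, 0.3, 0.2), pops),
                          150, seed = 96)
  p <- assignment_posteriors(mix$geno, b$geno)
  mp <- estimate_mixture(p, method = "mean-posterior")
  em <- estimate_mixture(p, method = "em")
  expect_true(all(abs(mp$pi[match(em$unit, mp$unit)] - em$pi) < 0.01))
})

test_that("major contributors are flagged at the threshold without dropping units", {
  est <- tibble::tibble(unit = c("a", "b", "c"), pi = c(0.71, 0.09, 0.20),
                        n_map = c(71L, 9L, 20L))
  class(est) <- c("gsi_mixture", class(est))
  attr(est, "method") <- "mean-posterior"
  rep10 <- report_major_contributors(est, 0.10)
  expect_equal(nrow(rep10), 3)
  expect_true(rep10$major[rep10$unit == "a"])
  expect_false(rep10$major[rep10$unit == "b"])
  expect_true(rep10$major[rep10$unit == "c"])
  rep0 <- report_major_contributors(est, 0)
  expect_true(all(rep0$major))
  # lowering the threshold can only grow the major set
  rep05 <- report_major_contributors(est, 0.05)
  expect_true(all(rep10$unit[rep10$major] %in% rep05$unit[rep05$major]))
})
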