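test_that("admixed frequencies are the arithmetic mean of source estimates", {
  g <- dplyr::bind_rows(
    toy_geno("A", L1 = replicate(10, c(1, 1), simplify = FALSE)),
    toy_geno("B", L1 = replicate(10, c(2, 2), simplify = FALSE))
  )
  f <- build_admixed_frequencies(g, "A", "B")
  expect_equal(f$freq, c(0.5, 0.5))

  # identical sources reproduce the source frequencies
  g2 <- dplyr::bind_rows(
    toy_geno("A", L1 = c(replicate(9, c(1, 1), simplify = FALSE),
                         list(c(1, 2)))),
    toy_geno("B", L1 = c(replicate(9, c(1, 1), simplify = FALSE),
                         list(c(1, 2))))
  )
  f2 <- build_admixed_frequencies(g2, "A", "B")
  expect_equal(f2$freq[f2$allele == 1], 0.95)

  # p_A = (0.9, 0.1), p_B = (0.5, 0.5) -> (0.7, 0.3)
  g3 <- dplyr::bind_rows(
    toy_geno("A", L1 = c(replicate(4, c(1, 1), simplify = FALSE),
                         list(c(1, 2)))),
    toy_geno("B", L1 = c(replicate(5, c(1, 2), simplify = FALSE)))
  )
  f3 <- build_admixed_frequencies(g3, "A", "B")
  expect_equal(f3$freq, c(0.7, 0.3), tolerance = 1e-12)

  # loci unscored in one source are dropped with a warning
  g4 <- dplyr::bind_rows(
    toy_geno("A", L1 = list(c(1, 2)), L2 = list(c(3, 4))),
    toy_geno("B", L1 = list(c(1, 2)), L2 = list(c(NA, NA)))
  )
  expect_warning(f4 <- build_admixed_frequencies(g4, "A", "B"), "L2")
  expect_false("L2" %in% f4$locus)
})

test_that("HWE sampling is degenerate, consistent and reproducible", {
  freqs <- tibble::tibble(locus = "L1", allele = c(1L, 2L), freq = c(1, 0))
  g <- sample_hwe_genotypes(freqs, 20, seed = 1)
  expect_true(all(g$allele_1 == 1 & g$allele_2 == 1))

  freqs2 <- tibble::tibble(locus = "L1", allele = c(1L, 2L, 3L),
                           freq = c(0.5, 0.3, 0.2))
  big <- sample_hwe_genotypes(freqs2, 10000, seed = 2)
  obs <- allele_counts(big)
  expect_true(all(abs(obs$freq - freqs2$freq) < 0.02))

  expect_equal(sample_hwe_genotypes(freqs2, 50, seed = 7),
               sample_hwe_genotypes(freqs2, 50, seed = 7))
  expect_error(sample_hwe_genotypes(freqs2, 0), "at least 1")
})

test_that("assignment categories partition and count fabricated posteriors correctly", {
  # 6 true, 3 sister, 1 unrelated at P = 0.9
  units <- c("T", "S", "U")
  mk_row <- function(i, unit, p) {
    q <- setNames(rep((1 - p) / 2, 3), units)
    q[unit] <- p
    tibble::tibble(collection = "sim", indiv = sprintf("f%02d", i),
                   unit = units, posterior = as.numeric(q),
                   n_loci = 10L, unassignable = FALSE, tie = FALSE)
  }
  rows <- c(lapply(1:6, mk_row, unit = "T", p = 0.9),
            lapply(7:9, mk_row, unit = "S", p = 0.9),
            lapply(10, mk_row, unit = "U", p = 0.9))
  post <- dplyr::bind_rows(rows)
  class(post) <- c("gsi_posterior", class(post))
  attr(post, "level") <- "group"
  rep <- categorize_assignments(
    post, truth_groups = "T",
    sisters = tibble::tibble(group = "T", sister = "S"),
    p_threshold = 0.8
  )
  expect_equal(as.numeric(rep$fractions), c(0.6, 0.3, 0.1))
  expect_equal(sum(rep$fractions), 1, tolerance = 1e-12)
  expect_equal(rep$fraction_unrelated_highconf, 1)

  # exhaustive truth: nothing is unrelated
  rep2 <- categorize_assignments(post, truth_groups = units,
                                 sisters = tibble::tibble(group = character(),
                                                          sister = character()))
  expect_equal(rep2$fractions[["unrelated"]], 0)
  expect_true(is.na(rep2$fraction_unrelated_highconf))

  expect_error(
    categorize_assignments(post, truth_groups = "absent",
                           sisters = tibble::tibble(group = character(),
                                                    sister = character())),
    "absent"
  )
})

test_that("founding simulation is deterministic and sends iid-source fish home", {
  b <- generate_baseline(baseline_spec(
    n_groups = 6, pops_per_group = 1, f_between = 0.2, f_within = 1e-4,
    n_loci = 8, alleles_per_locus = 8, n_per_pop = 40, seed = 120
  ))
  r1 <- run_founding_simulation(b$geno, b$hierarchy, "Group01_Pop1",
                                "Group02_Pop1", n = 100, seed = 121)
  r2 <- run_founding_simulation(b$geno, b$hierarchy, "Group01_Pop1",
                                "Group02_Pop1", n = 100, seed = 121)
  expect_equal(glance(r1), glance(r2))
  expect_equal(r1$per_group, r2$per_group)
  expect_equal(sum(r1$fractions), 1, tolerance = 1e-12)
  expect_true(all(r1$fractions >= 0 & r1$fractions <= 1))
  # pure controls are attached, one per source
  expect_equal(names(r1$pure_controls), c("Group01_Pop1", "Group02_Pop1"))
  # highly divergent truth groups: pure fish overwhelmingly assign true
  expect_gt(r1$pure_controls[[1]]$fractions[["true"]], 0.9)
  expect_error(
    run_founding_simulation(b$geno, b$hierarchy, "Group01_Pop1",
                            "Group01_Pop1", n = 10),
    "distinct"
  )
})

test_that("sources with identical frequencies make admixed fish behave like pure fish", {
  # two sources drawn at negligible divergence; everything else far away
  b <- generate_baseline(baseline_spec(
    n_groups = 4, pops_per_group = 1, f_between = 0.15, f_within = 1e-4,
    n_loci = 8, alleles_per_locus = 8, n_per_pop = 40, seed = 130
  ))
  # make source B a fresh iid sample from source A's true frequencies
  fa <- b$truth_freqs[b$truth_freqs$population == "Group01_Pop1", ]
  clone <- sample_hwe_genotypes(
    fa[, c("locus", "allele", "freq")], 40,
    collection_id = "CloneOfA", seed = 131
  )
  geno <- dplyr::bind_rows(b$geno, clone)
  hier <- dplyr::bind_rows(b$hierarchy,
                           tibble::tibble(population = "CloneOfA",
                                          group = "GroupClone"))
  r <- run_founding_simulation(geno, hier, "Group01_Pop1", "CloneOfA",
                               n = 300, seed = 132)
  truth_frac <- r$fractions[["true"]]
  pure_frac <- mean(vapply(r$pure_controls,
                           function(p) p$fractions[["true"]], numeric(1)))
  expect_lt(abs(truth_frac - pure_frac), 0.1)
})

test_that("admixture inflates unrelated-group misassignment in the sister scenario", {
  sc <- generate_sister_scenario(n_unrelated = 20, n_per_pop = 40, seed = 140)
  r <- run_founding_simulation(sc$geno, sc$hierarchy, sc$source_a, sc$source_b,
                               sisters = sc$sisters, n = 300, seed = 141)
  pure_unrel <- mean(vapply(r$pure_controls,
                            function(p) p$fractions[["unrelated"]], numeric(1)))
  expect_gt(r$fractions[["unrelated"]], pure_unrel)
  expect_gt(r$fractions[["true"]], 0.3)
})
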