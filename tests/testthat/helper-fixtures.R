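# Shared fixture builders and independent oracles.

# Build a one-locus (or multi-locus) genotype tibble from lists of allele
# pairs: toy_geno("P1", L1 = list(c(1,2), c(1,1)), L2 = ...)
toy_geno <- function(pop, ...) {
  loci <- list(...)
  rows <- lapply(names(loci), function(l) {
    gl <- loci[[l]]
    tibble::tibble(
      collection = pop,
      indiv = paste0(pop, "_", seq_along(gl)),
      locus = l,
      allele_1 = vapply(gl, function(g) as.integer(g[1]), integer(1)),
      allele_2 = vapply(gl, function(g) as.integer(g[2]), integer(1))
    )
  })
  dplyr::bind_rows(rows)
}

# Independent oracle for the Rannala-Mountain genotype probability:
# sequential Polya-urn enumeration of the two ordered allele draws, with
# prior mass 1/k per allele class.
rm_urn_oracle <- function(genotype, counts, k = length(counts)) {
  alpha <- counts + 1 / k
  n <- sum(counts)
  draw2 <- function(x, y) {
    (alpha[x] / (n + 1)) * ((alpha[y] + as.numeric(x == y)) / (n + 2))
  }
  a <- genotype[1]
  b <- genotype[2]
  if (a == b) draw2(a, a) else draw2(a, b) + draw2(b, a)
}

# Random small genotype dataset for round-trip property tests.
random_dataset <- function(seed, n_pops = 2, n_loci = 3, n_ind = 4,
                           missing_rate = 0.15) {
  withr::with_seed(seed, {
    rows <- list()
    for (p in seq_len(n_pops)) {
      for (i in seq_len(n_ind)) {
        for (l in seq_len(n_loci)) {
          miss <- runif(1) < missing_rate
          a <- if (miss) c(NA_integer_, NA_integer_) else
            sort(sample(100:120, 2, replace = TRUE))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            collection = sprintf("pop%d", p),
            indiv = sprintf("pop%d_ind%02d", p, i),
            locus = sprintf("Loc%02d", l),
            allele_1 = as.integer(a[1]), allele_2 = as.integer(a[2])
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}
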