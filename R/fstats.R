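#' Weir-Cockerham F-statistics
#'
#' Multilocus estimators of F_ST (theta) and F_IS (f) from the
#' among-population (a), among-individual-within-population (b) and
#' within-individual (c) variance components, computed per locus and allele
#' and combined as ratios of summed components (ratio-of-sums, not
#' mean-of-ratios):
#' `theta = sum(a) / sum(a + b + c)` and `f = 1 - sum(c) / sum(b + c)`.
#' Per locus, only individuals scored there enter the component formulas.
#'
#' @param geno Genotype tibble with at least two collections.
#' @param pops Optional subset/order of collections to use.
#' @return An object of class `wc_fst`: a list with `theta`, `f`, a
#'   per-locus tibble (`locus`, `a`, `b`, `c`, `theta`, `f`), the number of
#'   populations and loci, and `undefined` (TRUE when every locus is
#'   monomorphic so the estimators have no information).  `tidy()` returns
#'   the per-locus table; `glance()` the multilocus summary.
#' @export
weir_cockerham <- function(geno, pops = NULL) {
  check_genotypes(geno)
  pops <- pops %||% unique(geno$collection)
  if (length(pops) < 2L) abort("need at least two collections for theta.")
  geno <- geno[geno$collection %in% pops, ]
  registry <- locus_registry(geno)
  reg <- registry_list(registry)
  loci <- locus_order(geno)
  per_locus <- purrr::map(loci, function(l) {
    comp <- wc_components_locus(geno[geno$locus == l, ], pops, reg[[l]])
    tibble(locus = l, a = unname(comp["a"]), b = unname(comp["b"]),
           c = unname(comp["c"]))
  }) %>% dplyr::bind_rows()
  per_locus <- per_locus %>%
    mutate(
      theta = ifelse(.data$a + .data$b + .data$c != 0,
                     .data$a / (.data$a + .data$b + .data$c), NA_real_),
      f = ifelse(.data$b + .data$c != 0,
                 1 - .data$c / (.data$b + .data$c), NA_real_)
    )
  denom_t <- sum(per_locus$a + per_locus$b + per_locus$c, na.rm = TRUE)
  denom_f <- sum(per_locus$b + per_locus$c, na.rm = TRUE)
  undefined <- denom_t == 0
  out <- list(
    theta = if (undefined) NA_real_ else sum(per_locus$a, na.rm = TRUE) / denom_t,
    f = if (denom_f == 0) NA_real_ else 1 - sum(per_locus$c, na.rm = TRUE) / denom_f,
    per_locus = per_locus,
    n_pops = length(pops),
    n_loci = length(loci),
    undefined = undefined
  )
  class(out) <- "wc_fst"
  out
}

# variance components for one locus, summed over alleles
# returns c(a =, b =, c =)
wc_components_locus <- function(geno_l, pops, alleles) {
  k <- length(alleles)
  scored <- geno_l[!is.na(geno_l$allele_1), ]
  n_i <- vapply(pops, function(p) sum(scored$collection == p), numeric(1))
  use <- n_i > 0
  r <- sum(use)
  if (r < 2L || sum(n_i) == 0) return(c(a = 0, b = 0, c = 0))
  n_i <- n_i[use]
  pops <- pops[use]
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  a_tot <- b_tot <- c_tot <- 0
  pop_of <- match(scored$collection, pops)
  for (u in seq_len(k)) {
    al <- alleles[u]
    dose <- (scored$allele_1 == al) + (scored$allele_2 == al)
    het <- (scored$allele_1 == al) != (scored$allele_2 == al)
    cnt <- vapply(seq_along(pops), function(j) sum(dose[pop_of == j]), numeric(1))
    p_i <- cnt / (2 * n_i)
    h_i <- vapply(seq_along(pops), function(j) sum(het[pop_of == j]), numeric(1)) / n_i
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    if (nbar <= 1) next
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    a_tot <- a_tot + a
    b_tot <- b_tot + b
    c_tot <- c_tot + cc
  }
  c(a = a_tot, b = b_tot, c = c_tot)
}

#' @export
print.wc_fst <- function(x, ...) {
  cat("Weir-Cockerham multilocus estimates over", x$n_pops, "populations,",
      x$n_loci, "loci\n")
  cat(sprintf("  theta (F_ST): %s\n", format(x$theta, digits = 4)))
  cat(sprintf("  f     (F_IS): %s\n", format(x$f, digits = 4)))
  if (x$undefined) cat("  note: all loci monomorphic; estimates undefined\n")
  invisible(x)
}

#' @export
tidy.wc_fst <- function(x, ...) x$per_locus

#' @export
glance.wc_fst <- function(x, ...) {
  tibble(theta = x$theta, f = x$f, n_pops = x$n_pops, n_loci = x$n_loci,
         undefined = x$undefined)
}

#' Pairwise F_ST matrix
#'
#' Applies [weir_cockerham()] to every unordered pair of collections.
#'
#' @param geno Genotype tibble.
#' @param pops Optional subset/order of collections.
#' @return A tibble `pop_a`, `pop_b`, `theta` covering each unordered pair
#'   once, with attribute `"matrix"`: the symmetric matrix with zero
#'   diagonal.
#' @export
pairwise_fst <- function(geno, pops = NULL) {
  check_genotypes(geno)
  pops <- pops %||% unique(geno$collection)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  rows <- list()
  if (length(pops) >= 2L) {
    for (i in seq_len(length(pops) - 1L)) {
      for (j in (i + 1L):length(pops)) {
        th <- weir_cockerham(
          geno[geno$collection %in% pops[c(i, j)], ],
          pops = pops[c(i, j)]
        )$theta
        m[i, j] <- m[j, i] <- th
        rows[[length(rows) + 1L]] <-
          tibble(pop_a = pops[i], pop_b = pops[j], theta = th)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "matrix") <- m
  out
}
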