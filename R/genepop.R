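#' Read a GENEPOP genotype file
#'
#' Parses diploid multilocus genotypes in the GENEPOP text format used for
#' microsatellite baselines: a title line, one locus name per line (or a
#' single comma-separated line), then `POP` blocks of
#' `indiv_id , g1 g2 ...` records where each genotype token concatenates the
#' two allele codes in fixed width.  The all-zero code (`0000` / `000000`)
#' denotes a missing genotype.
#'
#' Population ids default to the label of the last individual in each block
#' (the common GENEPOP convention); pass `pop_ids` to name blocks by order
#' instead.
#'
#' @param path Path to the GENEPOP file.
#' @param allele_digits Digits per allele code, 2 or 3.
#' @param pop_ids Optional character vector naming the POP blocks in file
#'   order; lengths must agree.
#' @return A genotype tibble with columns `collection`, `indiv`, `locus`,
#'   `allele_1`, `allele_2` (integer allele codes; both `NA` when missing).
#'   The attribute `"loci"` carries locus names in file order.
#' @export
read_genepop <- function(path, allele_digits = 3, pop_ids = NULL) {
  if (!allele_digits %in% c(2L, 3L)) {
    abort("`allele_digits` must be 2 or 3.")
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*$", lines)
  orig_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 3L) abort("GENEPOP file too short: need title, loci, POP.")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) abort("GENEPOP file has no POP separator.")
  header <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) abort("GENEPOP file declares no loci.")
  if (anyDuplicated(loci)) abort("duplicate locus names in GENEPOP header.")

  pop_starts <- which(is_pop)
  n_pop <- length(pop_starts)
  if (!is.null(pop_ids) && length(pop_ids) != n_pop) {
    abort(sprintf("`pop_ids` has %d names but the file has %d POP blocks.",
                  length(pop_ids), n_pop))
  }
  width <- as.integer(allele_digits)
  rows <- vector("list", n_pop)
  line_no <- orig_no  # original file line numbers for error messages

  for (b in seq_len(n_pop)) {
    from <- pop_starts[b] + 1L
    to <- if (b < n_pop) pop_starts[b + 1L] - 1L else length(lines)
    if (to < from) abort(sprintf("POP block %d is empty.", b))
    block <- lines[from:to]
    ids <- character(length(block))
    mat1 <- matrix(NA_integer_, nrow = length(block), ncol = length(loci))
    mat2 <- mat1
    for (j in seq_along(block)) {
      ln <- block[j]
      pieces <- strsplit(ln, ",", fixed = TRUE)[[1]]
      if (length(pieces) < 2L) {
        abort(sprintf("line %d: expected 'id , genotypes' record.",
                      line_no[from + j - 1L]))
      }
      ids[j] <- trimws(pieces[1])
      toks <- strsplit(trimws(paste(pieces[-1], collapse = ",")), "\\s+")[[1]]
      toks <- toks[nzchar(toks)]
      if (length(toks) != length(loci)) {
        abort(sprintf("line %d: %d genotype tokens for %d loci.",
                      line_no[from + j - 1L], length(toks), length(loci)))
      }
      bad_width <- nchar(toks) != 2L * width
      if (any(bad_width)) {
        abort(sprintf(
          "line %d: genotype token '%s' is not %d characters wide.",
          line_no[from + j - 1L], toks[which(bad_width)[1]], 2L * width
        ))
      }
      a1 <- suppressWarnings(as.integer(substr(toks, 1L, width)))
      a2 <- suppressWarnings(as.integer(substr(toks, width + 1L, 2L * width)))
      if (anyNA(a1) || anyNA(a2)) {
        abort(sprintf("line %d: non-numeric allele code.",
                      line_no[from + j - 1L]))
      }
      miss <- a1 == 0L | a2 == 0L
      a1[miss] <- NA_integer_
      a2[miss] <- NA_integer_
      mat1[j, ] <- a1
      mat2[j, ] <- a2
    }
    pop_id <- if (is.null(pop_ids)) ids[length(ids)] else pop_ids[b]
    rows[[b]] <- tibble(
      collection = pop_id,
      indiv = rep(ids, each = length(loci)),
      locus = rep(loci, times = length(ids)),
      allele_1 = as.integer(t(mat1)),
      allele_2 = as.integer(t(mat2))
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "loci") <- loci
  out
}

#' Write genotypes to a GENEPOP file
#'
#' Missing genotypes are written as all-zero codes.  Round-trips with
#' [read_genepop()]: reading the written file reproduces the calls table.
#'
#' @param geno Genotype tibble (`collection`, `indiv`, `locus`, `allele_1`,
#'   `allele_2`).
#' @param path Output path.
#' @param allele_digits Digits per allele code, 2 or 3; every allele label
#'   must be < 10^allele_digits.
#' @param title Title line for the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(geno, path, allele_digits = 3,
                          title = "gsimix genotypes") {
  check_genotypes(geno)
  if (!allele_digits %in% c(2L, 3L)) abort("`allele_digits` must be 2 or 3.")
  labels <- c(geno$allele_1, geno$allele_2)
  labels <- labels[!is.na(labels)]
  if (length(labels) && max(labels) >= 10^allele_digits) {
    abort(sprintf("allele label %d does not fit in %d digits.",
                  max(labels), allele_digits))
  }
  if (length(labels) && min(labels) < 1) {
    abort("allele labels must be positive (0 is reserved for missing).")
  }
  loci <- attr(geno, "loci") %||% locus_order(geno)
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = allele_digits, flag = "0")
  }
  out <- c(title, loci)
  for (pop in unique(geno$collection)) {
    out <- c(out, "POP")
    sub <- geno[geno$collection == pop, ]
    for (id in unique(sub$indiv)) {
      g <- sub[sub$indiv == id, ]
      g <- g[match(loci, g$locus), ]
      toks <- paste0(fmt(g$allele_1), fmt(g$allele_2))
      out <- c(out, paste0(id, " ,  ", paste(toks, collapse = " ")))
    }
  }
  readr::write_lines(out, path)
  invisible(path)
}

#' Load a population-to-reporting-group hierarchy table
#'
#' Reads a delimited table mapping each baseline population to exactly one
#' reporting group, with an optional third column of sister tags: groups
#' sharing a tag are recorded as a symmetric sister pair (closely related
#' lineages expected to absorb benign misassignments).
#'
#' @param path Path to a TSV/CSV with columns `population`, `group` and
#'   optionally `sister_tag` (header required).
#' @return A tibble `population`, `group` (+ `sister_tag` if present), with
#'   attribute `"sisters"`: a symmetric tibble `group`, `sister`.
#' @export
load_hierarchy <- function(path) {
  tab <- readr::read_delim(path, show_col_types = FALSE, trim_ws = TRUE)
  names(tab)[1:2] <- c("population", "group")
  if (anyDuplicated(tab$population)) {
    abort("duplicate population rows in hierarchy table.")
  }
  sisters <- tibble(group = character(), sister = character())
  if (ncol(tab) >= 3L) {
    names(tab)[3] <- "sister_tag"
    sisters <- sister_pairs(tab)
  }
  out <- as_tibble(tab)
  attr(out, "sisters") <- sisters
  out
}

#' Derive symmetric sister-group pairs from sister tags
#'
#' @param hierarchy A hierarchy tibble with columns `group` and `sister_tag`.
#' @return Tibble `group`, `sister` containing both orientations of every
#'   pair (irreflexive, symmetric).
#' @export
sister_pairs <- function(hierarchy) {
  if (!"sister_tag" %in% names(hierarchy)) {
    return(tibble(group = character(), sister = character()))
  }
  tags <- dplyr::distinct(hierarchy[!is.na(hierarchy$sister_tag) &
                                      nzchar(hierarchy$sister_tag),
                                    c("group", "sister_tag")])
  out <- list()
  for (tg in unique(tags$sister_tag)) {
    gs <- unique(tags$group[tags$sister_tag == tg])
    if (length(gs) < 2L) next
    pairs <- expand.grid(group = gs, sister = gs, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$group != pairs$sister, ]
    out[[tg]] <- pairs
  }
  if (!length(out)) return(tibble(group = character(), sister = character()))
  as_tibble(dplyr::distinct(dplyr::bind_rows(out)))
}

#' Validate a baseline against its hierarchy
#'
#' Every collection id in the genotype table must appear as a population in
#' the hierarchy.
#'
#' @param geno Baseline genotype tibble.
#' @param hierarchy Hierarchy tibble (`population`, `group`).
#' @return `geno`, invisibly.
#' @export
validate_baseline <- function(geno, hierarchy) {
  check_genotypes(geno)
  missing <- setdiff(unique(geno$collection), hierarchy$population)
  if (length(missing)) {
    abort(sprintf("population(s) absent from hierarchy: %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(geno)
}

#' Pool genotype collections into one
#'
#' Concatenates the individuals of several collections under a new id.  The
#' pooled collection's allele counts equal the sum of member counts at every
#' locus and allele; used e.g. to aggregate sampling locations within a river
#' basin when their allele frequencies are not significantly different.
#'
#' @param geno Genotype tibble.
#' @param ids Collection ids to pool.
#' @param new_id Id for the pooled collection.
#' @return Genotype tibble with the members replaced by one pooled
#'   collection; other collections pass through unchanged.
#' @export
pool_collections <- function(geno, ids, new_id) {
  check_genotypes(geno)
  present <- unique(geno$collection)
  missing <- setdiff(ids, present)
  if (length(missing)) {
    abort(sprintf("collection(s) not found: %s", paste(missing, collapse = ", ")))
  }
  loci_by_pop <- lapply(ids, function(p) sort(unique(geno$locus[geno$collection == p])))
  if (length(unique(loci_by_pop)) > 1L) {
    abort("collections to pool do not share a locus registry.")
  }
  pooled <- geno$collection %in% ids
  out <- geno
  # disambiguate repeated individual ids across member collections
  out$indiv[pooled] <- paste(out$collection[pooled], out$indiv[pooled], sep = ".")
  out$collection[pooled] <- new_id
  attr(out, "loci") <- attr(geno, "loci")
  out
}
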