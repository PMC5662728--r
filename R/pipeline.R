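#' Run the full stock-identification study workflow
#'
#' Orchestrates, in order: load and validate the baseline, hierarchy and
#' mixture; pool collections; diversity and F-statistics plus pairwise
#' differentiation tests (with the popgen locus exclusions); leave-one-out
#' self-assignment; mixture assignment, group aggregation, mixture estimate
#' and major-contributor table (assignment keeps all loci unless an
#' assignment-specific exclusion is given); and, optionally, the
#' mixed-origin founding simulation.  Every artifact is written as TSV/JSON
#' with the seed and a config hash, so a rerun with the same config is
#' bitwise identical.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{baseline, mixture}{genotype tibbles, or paths to GENEPOP files}
#'     \item{hierarchy}{hierarchy tibble or path to a TSV}
#'     \item{sisters}{optional sister-pair tibble or TSV path}
#'     \item{pool}{optional named list: new id -> character vector of member
#'       collection ids}
#'     \item{exclude_loci_popgen, exclude_loci_assignment}{optional locus
#'       exclusion lists for the two stages}
#'     \item{g}{rarefaction gene copies (default 24)}
#'     \item{n_perm}{permutations for differentiation tests (default 999;
#'       0 skips them)}
#'     \item{mixture_method}{"mean-posterior" or "em"}
#'     \item{threshold}{major-contributor cutoff (default 0.10)}
#'     \item{founding}{optional list(source_a, source_b, n, p_threshold)}
#'     \item{seed}{global seed; per-stage substreams are derived from it}
#'     \item{allele_digits}{GENEPOP allele width when reading paths (default 3)}
#'   }
#' @param out_dir Output directory for the artifact bundle.
#' @return Invisibly, a list of the in-memory results
#'   (`diversity`, `fst`, `pairwise`, `diff_tests`, `confusion`,
#'   `posteriors`, `mixture`, `founding`, `meta`).
#' @export
run_study <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  cfg_hash <- digest::digest(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  load_geno <- function(x, digits) {
    if (is.character(x)) read_genepop(x, allele_digits = digits) else {
      check_genotypes(x)
      x
    }
  }
  digits <- config$allele_digits %||% 3
  baseline <- stage("load", load_geno(config$baseline, digits))
  hierarchy <- stage("load", {
    if (is.character(config$hierarchy)) load_hierarchy(config$hierarchy)
    else config$hierarchy
  })
  sisters <- stage("load", {
    s <- config$sisters
    if (is.null(s)) attr(hierarchy, "sisters") %||%
      tibble(group = character(), sister = character())
    else if (is.character(s)) {
      tab <- readr::read_tsv(s, show_col_types = FALSE)
      names(tab)[1:2] <- c("group", "sister")
      dplyr::bind_rows(tab, tibble(group = tab$sister, sister = tab$group)) %>%
        dplyr::distinct()
    } else s
  })
  mixture <- if (!is.null(config$mixture)) {
    stage("load", load_geno(config$mixture, digits))
  } else NULL

  if (!is.null(config$pool)) {
    baseline <- stage("pool", {
      for (new_id in names(config$pool)) {
        baseline <- pool_collections(baseline, config$pool[[new_id]], new_id)
      }
      baseline
    })
  }
  stage("validate", validate_baseline(baseline, hierarchy))

  ex_pop <- config$exclude_loci_popgen %||% character(0)
  ex_asn <- config$exclude_loci_assignment %||% character(0)
  popgen_geno <- baseline[!baseline$locus %in% ex_pop, ]
  attr(popgen_geno, "loci") <- setdiff(attr(baseline, "loci") %||%
                                         locus_order(baseline), ex_pop)

  diversity <- stage("diversity", diversity_summary(popgen_geno, g = config$g %||% 24))
  fst <- stage("fstats", weir_cockerham(popgen_geno))
  pw <- stage("fstats", pairwise_fst(popgen_geno))

  n_perm <- config$n_perm %||% 999
  diff_tests <- NULL
  if (n_perm >= 99) {
    diff_tests <- stage("diff-tests", {
      pops <- unique(popgen_geno$collection)
      rows <- list()
      idx <- 0L
      for (i in seq_len(length(pops) - 1L)) {
        for (j in (i + 1L):length(pops)) {
          idx <- idx + 1L
          rows[[idx]] <- genic_differentiation_test(
            popgen_geno, pops[i], pops[j], n_perm = n_perm,
            seed = substream(seed, 100 + idx)
          )
        }
      }
      dplyr::bind_rows(rows)
    })
  }

  confusion <- stage("self-assign",
                     self_assignment_confusion(baseline[!baseline$locus %in% ex_asn, ],
                                               hierarchy, level = "group"))

  posteriors <- mixture_est <- major <- NULL
  if (!is.null(mixture)) {
    asn_base <- baseline[!baseline$locus %in% ex_asn, ]
    asn_mix <- mixture[!mixture$locus %in% ex_asn, ]
    posteriors <- stage("assign", assignment_posteriors(asn_mix, asn_base))
    gpost <- stage("assign", aggregate_to_groups(posteriors, hierarchy))
    mixture_est <- stage("mixture", estimate_mixture(
      gpost, method = config$mixture_method %||% "mean-posterior"
    ))
    major <- report_major_contributors(mixture_est,
                                       threshold = config$threshold %||% 0.10)
  }

  founding <- NULL
  if (!is.null(config$founding)) {
    fc <- config$founding
    founding <- stage("founding-sim", run_founding_simulation(
      baseline[!baseline$locus %in% ex_asn, ], hierarchy,
      source_a = fc$source_a, source_b = fc$source_b, sisters = sisters,
      n = fc$n %||% 1000, p_threshold = fc$p_threshold %||% 0.8,
      seed = substream(seed, 7)
    ))
  }

  meta <- list(
    seed = seed, config_hash = cfg_hash,
    exclude_loci_popgen = ex_pop, exclude_loci_assignment = ex_asn,
    loci_popgen = unique(popgen_geno$locus),
    loci_assignment = setdiff(unique(baseline$locus), ex_asn),
    unassignable = if (!is.null(posteriors)) {
      unique(posteriors$indiv[posteriors$unassignable])
    } else character(0),
    timestamp = NULL
  )

  # -- write bundle ---------------------------------------------------------
  w <- function(df, name) readr::write_tsv(df, file.path(out_dir, name))
  w(diversity, "diversity.tsv")
  w(tidy(fst), "fst_per_locus.tsv")
  w(pw, "pairwise_fst.tsv")
  if (!is.null(diff_tests)) w(diff_tests, "diff_tests.tsv")
  w(as_tibble(confusion), "confusion.tsv")
  if (!is.null(posteriors)) {
    w(as_tibble(posteriors), "posteriors.tsv")
    w(as_tibble(major), "mixture.tsv")
  }
  if (!is.null(founding)) {
    jsonlite::write_json(
      list(fractions = as.list(founding$fractions),
           fraction_unrelated_highconf = founding$fraction_unrelated_highconf,
           per_group = founding$per_group,
           pure_controls = lapply(founding$pure_controls, function(p) {
             c(as.list(p$fractions),
               list(highconf = p$fraction_unrelated_highconf))
           }),
           spec = founding$spec),
      file.path(out_dir, "founding.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
    w(founding$per_group, "founding_per_group.tsv")
  }
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, null = "null")

  invisible(list(diversity = diversity, fst = fst, pairwise = pw,
                 diff_tests = diff_tests, confusion = confusion,
                 posteriors = posteriors, mixture = major,
                 founding = founding, meta = meta))
}
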