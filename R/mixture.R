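#' Mixture-proportion estimation from assignment posteriors
#'
#' Two estimators of the proportional contribution of each baseline unit
#' (population or reporting group) to a mixture sample:
#'
#' * `"mean-posterior"`: the mean over individuals of the equal-prior
#'   membership posterior — the first approximation of overall genetic
#'   ancestral contribution.
#' * `"em"`: conditional maximum likelihood by expectation-maximization.
#'   Because equal-prior posteriors are proportional to the conditional
#'   likelihoods, the update
#'   `pi_u <- (1/M) sum_i pi_u q_iu / sum_v pi_v q_iv`
#'   iterates from a uniform start until `max |delta pi| < tol` or
#'   `max_iter`; the observed-data log-likelihood is non-decreasing at every
#'   step.
#'
#' Individuals flagged unassignable (no scored loci) are excluded with a
#' message.  Individual counts are tabulated under maximum a posteriori with
#' the method's final priors (equal for mean-posterior, `pi` for EM).
#'
#' @param posteriors A `gsi_posterior` tibble (population or group level).
#' @param method `"mean-posterior"` (default) or `"em"`.
#' @param tol EM convergence tolerance on `max |delta pi|`.
#' @param max_iter Maximum EM iterations.
#' @return A `gsi_mixture` tibble: `unit`, `pi`, `n_map` (individuals
#'   allocated by maximum a posteriori).  Attributes: `method`, `n_indiv`,
#'   `level`, `log_lik` (EM trace, EM only), `converged`, `n_iter`.
#' @export
estimate_mixture <- function(posteriors, method = c("mean-posterior", "em"),
                             tol = 1e-6, max_iter = 10000) {
  method <- match.arg(method)
  units <- unique(posteriors$unit)
  wide <- tidyr::pivot_wider(
    posteriors[, c("collection", "indiv", "unit", "posterior")],
    names_from = "unit", values_from = "posterior"
  )
  q <- as.matrix(wide[, units, drop = FALSE])
  usable <- rowSums(is.na(q)) == 0
  if (!all(usable)) {
    inform(sprintf("%d individual(s) with no scored loci excluded from mixture estimation.",
                   sum(!usable)))
  }
  q <- q[usable, , drop = FALSE]
  if (!nrow(q)) abort("no scored individuals to estimate a mixture from.")
  m <- nrow(q)

  log_lik <- NULL
  converged <- TRUE
  n_iter <- 0L
  if (method == "mean-posterior") {
    pi_hat <- colMeans(q)
    w <- q  # equal priors for MAP counts
  } else {
    pi_hat <- setNames(rep(1 / ncol(q), ncol(q)), colnames(q))
    log_lik <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      num <- sweep(q, 2, pi_hat, "*")
      denom <- rowSums(num)
      log_lik <- c(log_lik, sum(log(denom)))
      w <- num / denom
      pi_new <- colMeans(w)
      delta <- max(abs(pi_new - pi_hat))
      pi_hat <- pi_new
      n_iter <- it
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    num <- sweep(q, 2, pi_hat, "*")
    w <- num / rowSums(num)
  }
  map_unit <- units[max.col(w, ties.method = "first")]
  n_map <- vapply(units, function(u) sum(map_unit == u), integer(1))
  out <- tibble(unit = units, pi = as.numeric(pi_hat[units]), n_map = n_map)
  class(out) <- c("gsi_mixture", class(out))
  attr(out, "method") <- method
  attr(out, "n_indiv") <- m
  attr(out, "level") <- attr(posteriors, "level") %||% "population"
  attr(out, "log_lik") <- log_lik
  attr(out, "converged") <- converged
  attr(out, "n_iter") <- n_iter
  out
}

#' Flag major contributors in a mixture estimate
#'
#' Units whose estimated proportion reaches the threshold are flagged
#' `major`; all units remain in the table.  The default 10% threshold
#' reflects the contribution level below which spurious assignment of
#' admixed fish can masquerade as a real signal.
#'
#' @param estimate A `gsi_mixture` tibble.
#' @param threshold Proportion in (0, 1); default 0.10.
#' @return The estimate with an added logical `major` column, sorted by
#'   decreasing `pi`.
#' @export
report_major_contributors <- function(estimate, threshold = 0.10) {
  if (threshold <= 0 || threshold >= 1) {
    if (threshold != 0) abort("`threshold` must be in (0, 1) (0 allowed to flag all).")
  }
  out <- estimate %>%
    mutate(major = .data$pi >= threshold) %>%
    dplyr::arrange(dplyr::desc(.data$pi))
  class(out) <- unique(c("gsi_mixture", class(out)))
  for (at in c("method", "n_indiv", "level", "log_lik", "converged", "n_iter")) {
    attr(out, at) <- attr(estimate, at)
  }
  attr(out, "threshold") <- threshold
  out
}

#' @export
tidy.gsi_mixture <- function(x, ...) as_tibble(x)

#' @export
glance.gsi_mixture <- function(x, ...) {
  tibble(
    method = attr(x, "method"),
    n_indiv = attr(x, "n_indiv"),
    n_units = nrow(x),
    level = attr(x, "level"),
    converged = attr(x, "converged") %||% TRUE,
    n_iter = attr(x, "n_iter") %||% 0L
  )
}

#' Bar plot of mixture proportions
#'
#' @param object A `gsi_mixture` tibble.
#' @param threshold Reference line for the major-contributor cutoff.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsi_mixture <- function(object, threshold = attr(object, "threshold") %||% 0.10,
                                 ...) {
  df <- as_tibble(object)
  df$unit <- factor(df$unit, levels = df$unit[order(df$pi)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pi, y = .data$unit)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "estimated contribution", y = NULL,
                  title = sprintf("Mixture composition (%s)", attr(object, "method"))) +
    ggplot2::theme_minimal()
}

#' Heatmap of a self-assignment confusion matrix
#'
#' @param object A `gsi_confusion` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsi_confusion <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$assigned_unit, y = .data$true_unit,
                               fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "assigned", y = "true", fill = "rate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
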