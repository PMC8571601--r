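#' Contribution filter from bootstrap-replicated preliminary fits
#'
#' Fits the model on `n_replicates` bootstrap resamples of the presences
#' (background fixed), averages the permutation contribution of each
#' variable across replicates, and retains variables whose mean contribution
#' exceeds `threshold_pct`.
#'
#' @param presences,background Occurrence tibbles.
#' @param stack Predictor stack.
#' @param n_replicates Bootstrap replicates (default 5).
#' @param threshold_pct Retention threshold in percent (default 3).
#' @param seed Integer seed.
#' @param spec,rm,maxit,tol Passed to [fit_maxent()].
#' @return Tibble `variable`, `mean_contribution`, `retained`, ordered by
#'   decreasing contribution.
#' @export
contribution_filter <- function(presences, background, stack,
                                n_replicates = 5, threshold_pct = 3, seed = 1,
                                spec = feature_spec("LQ"), rm = 1,
                                maxit = 10000, tol = 1e-6) {
  stopifnot(n_replicates >= 1)
  check_occurrences(presences)
  boots <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(i) {
      presences[sample.int(nrow(presences), nrow(presences), replace = TRUE), ]
    })
  })
  contribs <- purrr::imap(boots, function(b, i) {
    fit <- fit_maxent(b, background, stack, spec = spec, rm = rm,
                      maxit = maxit, tol = tol, on_nonconvergence = "warn")
    percent_contribution(fit, stack, seed = seed + i)
  })
  out <- dplyr::bind_rows(contribs)
  out <- dplyr::summarise(dplyr::group_by(out, .data$variable),
                          mean_contribution = mean(.data$contribution),
                          .groups = "drop")
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_contribution))
  out <- dplyr::mutate(out, retained = .data$mean_contribution > threshold_pct)
  if (!any(out$retained)) {
    stop("contribution filter removed every variable", call. = FALSE)
  }
  out
}

#' Prune correlated predictors by Spearman rank correlation
#'
#' Computes pairwise Spearman correlations over the shared valid cells of
#' the stack (average ranks for ties) and greedily keeps, within any pair
#' with `|rho| > cutoff`, the member appearing earlier in `priority`
#' (typically descending contribution). The retained set has no pair above
#' the cutoff, and the result does not depend on candidate input order.
#'
#' @param stack Predictor stack.
#' @param candidates Character vector of layer names to consider.
#' @param cutoff Absolute-correlation cutoff in (0, 1] (default 0.7).
#' @param priority Ordered character vector covering all candidates.
#' @return A `screen_report` list: `final_variables`, `dropped_pairs`
#'   (tibble `kept`, `dropped`, `rho`), `correlation_matrix`.
#' @export
spearman_prune <- function(stack, candidates, cutoff = 0.7,
                           priority = candidates) {
  stopifnot(cutoff > 0, cutoff <= 1)
  miss <- setdiff(candidates, names(stack$layers))
  if (length(miss)) stop("candidates not in stack: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  outside <- setdiff(candidates, priority)
  if (length(outside)) stop("priority omits candidate(s): ",
                            paste(outside, collapse = ", "), call. = FALSE)
  valid <- which(!stack$union_nodata)
  x <- vapply(stack$layers[candidates], function(l) l$values[valid],
              numeric(length(valid)))
  rho <- stats::cor(x, method = "spearman")
  ord <- priority[priority %in% candidates]
  kept <- character(0)
  dropped <- list()
  for (v in ord) {
    conflict <- kept[abs(rho[v, kept]) > cutoff]
    if (length(conflict)) {
      dropped[[length(dropped) + 1L]] <- tibble::tibble(
        kept = conflict[1], dropped = v, rho = rho[v, conflict[1]])
    } else {
      kept <- c(kept, v)
    }
  }
  structure(list(
    final_variables = kept,
    dropped_pairs = if (length(dropped)) dplyr::bind_rows(dropped) else
      tibble::tibble(kept = character(), dropped = character(), rho = numeric()),
    correlation_matrix = rho
  ), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d variables retained: %s\n",
              length(x$final_variables),
              paste(x$final_variables, collapse = ", ")))
  if (nrow(x$dropped_pairs)) {
    cat(sprintf("  dropped %d correlated variable(s)\n", nrow(x$dropped_pairs)))
  }
  invisible(x)
}

#' Two-step variable screen
#'
#' The full screening procedure: bootstrap-replicated contribution filter
#' (retain variables with mean contribution above `threshold_pct`) followed
#' by Spearman pruning of correlated pairs at `|rho| > cutoff`, with
#' priority given to higher mean contribution.
#'
#' @inheritParams contribution_filter
#' @param cutoff Spearman cutoff (default 0.7).
#' @return A `screen_report` with an extra `mean_contribution` tibble and
#'   `retained_after_contribution` character vector.
#' @export
screen_variables <- function(presences, background, stack,
                             n_replicates = 5, threshold_pct = 3,
                             cutoff = 0.7, seed = 1,
                             spec = feature_spec("LQ"), rm = 1,
                             maxit = 10000, tol = 1e-6) {
  contrib <- contribution_filter(presences, background, stack,
                                 n_replicates = n_replicates,
                                 threshold_pct = threshold_pct, seed = seed,
                                 spec = spec, rm = rm, maxit = maxit, tol = tol)
  cand <- contrib$variable[contrib$retained]
  rep <- spearman_prune(stack, cand, cutoff = cutoff, priority = cand)
  rep$mean_contribution <- contrib
  rep$retained_after_contribution <- cand
  rep
}
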