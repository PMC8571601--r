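#' Feature-class specification for the suitability model
#'
#' The model expands each predictor into MaxEnt-style features: linear (`L`),
#' quadratic (`Q`), pairwise products (`P`), threshold indicator steps (`T`)
#' and forward/reverse hinges (`H`). Knots are evenly spaced on the training
#' range; with `clamp = TRUE` predictor values are truncated to the training
#' range before expansion (recommended when projecting beyond the training
#' data, e.g. warmed climates).
#'
#' @param classes Character scalar or vector over `L`, `Q`, `H`, `P`, `T`
#'   (e.g. `"LQH"`).
#' @param n_hinge_knots Interior knots per variable for hinge features (>= 2
#'   when `H` used); each knot contributes a forward and a reverse hinge.
#' @param n_threshold_knots Interior knots per variable for threshold
#'   features (>= 2 when `T` used).
#' @param clamp Truncate to the training range before expansion.
#' @return A `feature_spec` list.
#' @export
feature_spec <- function(classes = "LQH", n_hinge_knots = 30,
                         n_threshold_knots = 30, clamp = TRUE) {
  cl <- unique(strsplit(paste(classes, collapse = ""), "")[[1]])
  bad <- setdiff(cl, c("L", "Q", "H", "P", "T"))
  if (length(bad)) {
    stop("unknown feature class tag: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!length(cl)) stop("feature classes must be non-empty", call. = FALSE)
  if ("H" %in% cl && n_hinge_knots < 2) stop("n_hinge_knots must be >= 2", call. = FALSE)
  if ("T" %in% cl && n_threshold_knots < 2) stop("n_threshold_knots must be >= 2", call. = FALSE)
  structure(list(classes = cl, n_hinge_knots = n_hinge_knots,
                 n_threshold_knots = n_threshold_knots, clamp = clamp),
            class = "feature_spec")
}

#' Expand predictors into model features
#'
#' Variables are min-max scaled to the training range (`z = (x - min) /
#' (max - min)`), then expanded per [feature_spec()]: `L -> z`, `Q -> z^2`,
#' `P -> z_i z_j` for all pairs, `T -> 1(z > k)`, `H ->` forward
#' `max(0, (z - k) / (1 - k))` and reverse `max(0, (k - z) / k)` at interior
#' knots `k = 1/(m+1), ..., m/(m+1)`.
#'
#' @param x Data frame or matrix of predictor values (named columns).
#' @param spec A [feature_spec()].
#' @param ranges Named list of `c(min, max)` training ranges per variable.
#' @return List with `F` (numeric feature matrix) and `meta` (tibble:
#'   `feature`, `class`, `var1`, `var2`, `knot`).
#' @export
expand_features <- function(x, spec, ranges) {
  x <- as.matrix(x)
  vars <- colnames(x)
  if (is.null(vars)) stop("predictor columns must be named", call. = FALSE)
  miss <- setdiff(vars, names(ranges))
  if (length(miss)) stop("missing training range for: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  z <- x
  for (v in vars) {
    r <- ranges[[v]]
    xv <- x[, v]
    if (spec$clamp) xv <- pmin(pmax(xv, r[1]), r[2])
    z[, v] <- if (r[2] > r[1]) (xv - r[1]) / (r[2] - r[1]) else 0
  }
  cols <- list(); meta <- list()
  add <- function(vals, feature, class, var1, var2 = NA_character_,
                  knot = NA_real_) {
    cols[[length(cols) + 1L]] <<- vals
    meta[[length(meta) + 1L]] <<- tibble::tibble(
      feature = feature, class = class, var1 = var1, var2 = var2, knot = knot)
  }
  if ("L" %in% spec$classes) for (v in vars) add(z[, v], paste0("L_", v), "L", v)
  if ("Q" %in% spec$classes) for (v in vars) add(z[, v]^2, paste0("Q_", v), "Q", v)
  if ("P" %in% spec$classes && length(vars) > 1L) {
    for (i in seq_len(length(vars) - 1L)) for (j in (i + 1L):length(vars)) {
      add(z[, i] * z[, j], paste0("P_", vars[i], "_", vars[j]), "P",
          vars[i], vars[j])
    }
  }
  if ("T" %in% spec$classes) {
    kn <- seq_len(spec$n_threshold_knots) / (spec$n_threshold_knots + 1)
    for (v in vars) for (k in kn) {
      add(as.numeric(z[, v] > k), sprintf("T_%s_%.4f", v, k), "T", v, knot = k)
    }
  }
  if ("H" %in% spec$classes) {
    kn <- seq_len(spec$n_hinge_knots) / (spec$n_hinge_knots + 1)
    for (v in vars) for (k in kn) {
      add(pmax(0, (z[, v] - k) / (1 - k)), sprintf("Hf_%s_%.4f", v, k), "H",
          v, knot = k)
      add(pmax(0, (k - z[, v]) / k), sprintf("Hr_%s_%.4f", v, k), "H",
          v, knot = k)
    }
  }
  F <- do.call(cbind, cols)
  meta <- dplyr::bind_rows(meta)
  colnames(F) <- meta$feature
  list(F = F, meta = meta)
}

# Per-class base regularization at m presences: MaxEnt-style interpolation
# on sample size for L/Q/P, constants for hinge (0.5) and threshold (1.0).
base_penalty <- function(class, m) {
  interp <- function(ns, vals) {
    if (m <= ns[1]) vals[1]
    else if (m >= ns[length(ns)]) vals[length(vals)]
    else stats::approx(ns, vals, xout = m)$y
  }
  switch(class,
         L = ,
         Q = interp(c(10, 30, 100), c(1.0, 0.2, 0.05)),
         P = interp(c(10, 30, 100), c(1.0, 0.2, 0.05)),
         H = 0.5,
         T = 1.0,
         stop("unknown feature class: ", class, call. = FALSE))
}

log_mean_exp <- function(x) { mx <- max(x); mx + log(mean(exp(x - mx))) }

#' Fit the penalized maximum-entropy suitability model
#'
#' Fits a Gibbs (log-linear) density over the background cells by maximizing
#' the L1-penalized average presence log-likelihood
#' `mean_presence(eta) - log mean_background(exp(eta)) - sum_j c_j |beta_j|`
#' with per-feature penalty `c_j = rm * base(class_j, m) * s_j / sqrt(m)`
#' (`s_j` = feature sd over the training sample, `m` = presence cells; the
#' `1/sqrt(m)` scaling is the standard MaxEnt default, shrinking the model
#' to near-uniform when the presences carry no signal), via
#' FISTA proximal gradient with backtracking on the convex objective.
#' Presence cells are collapsed to one record per cell and included among the
#' background; duplicated background cells are collapsed too.
#'
#' @param presences,background Occurrence tibbles (`lon`, `lat`).
#' @param stack An [align_stack()] predictor stack.
#' @param spec A [feature_spec()].
#' @param rm Regularization multiplier (> 0).
#' @param maxit Maximum FISTA iterations.
#' @param tol Convergence tolerance on the objective change (default 1e-7).
#' @param on_nonconvergence `"error"` (contractual) or `"warn"`.
#' @return An `sdm_maxent` model: sparse coefficients, feature metadata,
#'   training ranges, normalizer, entropy and training gain.
#' @export
fit_maxent <- function(presences, background, stack, spec = feature_spec(),
                       rm = 1, maxit = 10000, tol = 1e-7,
                       on_nonconvergence = c("error", "warn")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  stopifnot(rm > 0)
  check_occurrences(presences); check_occurrences(background)
  g <- stack$layers[[1]]

  cell_of <- function(occ) {
    rc <- cell_index(g, occ$lon, occ$lat)
    idx <- rc[, 1] + (rc[, 2] - 1L) * grid_nrow(g)
    idx[!is.na(idx) & !stack$union_nodata[idx]]
  }
  pcell <- unique(cell_of(presences))
  if (length(pcell) < 10L) {
    stop("need at least 10 presence cells on valid data", call. = FALSE)
  }
  bcell <- unique(c(cell_of(background), pcell))

  vals_at <- function(cells) {
    out <- vapply(stack$layers, function(l) l$values[cells],
                  numeric(length(cells)))
    if (is.null(dim(out))) out <- matrix(out, nrow = length(cells))
    colnames(out) <- names(stack$layers)
    out
  }
  Xp <- vals_at(pcell); Xb <- vals_at(bcell)
  vars <- colnames(Xp)
  ranges <- lapply(seq_along(vars), function(j) range(c(Xp[, j], Xb[, j])))
  names(ranges) <- vars

  fp <- expand_features(Xp, spec, ranges)
  fb <- expand_features(Xb, spec, ranges)
  s_all <- apply(rbind(fp$F, fb$F), 2L, stats::sd)
  keep <- s_all > 0
  if (!any(keep)) stop("all features are constant on the training data", call. = FALSE)
  Fp <- fp$F[, keep, drop = FALSE]; Fb <- fb$F[, keep, drop = FALSE]
  meta <- fp$meta[keep, , drop = FALSE]
  s <- s_all[keep]
  m <- length(pcell); B <- length(bcell)
  base <- vapply(meta$class, base_penalty, numeric(1), m = m)
  cj <- rm * base * s / sqrt(m)

  fbar <- colMeans(Fp)
  smooth_obj <- function(beta) {
    eta_b <- drop(Fb %*% beta)
    log_mean_exp(eta_b) - sum(fbar * beta)
  }
  smooth_grad <- function(beta) {
    eta_b <- drop(Fb %*% beta)
    w <- exp(eta_b - max(eta_b)); w <- w / sum(w)
    drop(crossprod(Fb, w)) - fbar
  }
  obj <- function(beta) smooth_obj(beta) + sum(cj * abs(beta))

  J <- ncol(Fp)
  beta <- numeric(J); y <- beta; t_k <- 1
  L <- 1
  f_prev <- obj(beta)
  converged <- FALSE; it <- 0L
  while (it < maxit) {
    it <- it + 1L
    gy <- smooth_grad(y); fy <- smooth_obj(y)
    repeat {
      cand <- y - gy / L
      cand <- sign(cand) * pmax(abs(cand) - cj / L, 0)
      d <- cand - y
      if (smooth_obj(cand) <= fy + sum(gy * d) + L / 2 * sum(d^2) + 1e-12) break
      L <- L * 2
    }
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    y <- cand + ((t_k - 1) / t_next) * (cand - beta)
    beta <- cand; t_k <- t_next
    L <- max(L / 1.5, 1e-4)
    f_cur <- obj(beta)
    if (f_cur > f_prev + 1e-10) { y <- beta; t_k <- 1 }   # FISTA restart
    if (abs(f_prev - f_cur) < tol) { converged <- TRUE; break }
    f_prev <- f_cur
  }
  if (!converged) {
    msg <- sprintf("maxent fit did not converge in %d iterations (last objective %.8g)",
                   maxit, f_prev)
    if (on_nonconvergence == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }

  eta_b <- drop(Fb %*% beta)
  lnZmean <- log_mean_exp(eta_b)
  p_b <- exp(eta_b - max(eta_b)); p_b <- p_b / sum(p_b)
  entropy_H <- -sum(ifelse(p_b > 0, p_b * log(p_b), 0))
  gain <- sum(fbar * beta) - lnZmean

  structure(list(
    beta = stats::setNames(beta, meta$feature), meta = meta, s = s,
    ranges = ranges, spec = spec, rm = rm, m = m, n_background = B,
    lnZmean = lnZmean, entropy_H = entropy_H, gain = gain,
    penalty = cj, iterations = it, converged = converged,
    vars = vars, presence_cells = pcell, background_cells = bcell
  ), class = "sdm_maxent")
}

#' @export
print.sdm_maxent <- function(x, ...) {
  cat(sprintf("<sdm_maxent> %s features, rm = %g, %d presence cells, %d background cells\n",
              paste(x$spec$classes, collapse = ""), x$rm, x$m, x$n_background))
  cat(sprintf("  non-zero coefficients: %d/%d; training gain %.4f; entropy %.4f\n",
              sum(x$beta != 0), length(x$beta), x$gain, x$entropy_H))
  invisible(x)
}

# Linear predictor eta at a matrix of raw predictor values.
model_eta <- function(model, x) {
  f <- expand_features(x[, model$vars, drop = FALSE], model$spec, model$ranges)
  drop(f$F[, model$meta$feature, drop = FALSE] %*% model$beta)
}

#' Predict suitability over a stack
#'
#' `raw` output is the Gibbs density normalized so that its mean over the
#' *training* background is 1 (the normalizer is frozen at training, so
#' projections to scenario stacks stay comparable). `cloglog` output maps raw
#' onto `[0, 1)` by `1 - exp(-exp(H) * raw / B)` where `H` is the entropy of
#' the fitted background distribution and `B` the background size (i.e. the
#' usual cloglog transform of the sum-to-one raw density); it is strictly
#' increasing in raw.
#'
#' @param object An [fit_maxent()] model.
#' @param stack Stack containing all model variables.
#' @param output `"cloglog"` (default) or `"raw"`.
#' @param ... Unused.
#' @return An [sdm_grid] of predictions (nodata propagated).
#' @export
predict.sdm_maxent <- function(object, stack, output = c("cloglog", "raw"), ...) {
  output <- match.arg(output)
  miss <- setdiff(object$vars, names(stack$layers))
  if (length(miss)) stop("stack is missing model variable(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  g <- stack$layers[[1]]
  valid <- which(!stack$union_nodata)
  x <- vapply(stack$layers[object$vars], function(l) l$values[valid],
              numeric(length(valid)))
  if (is.null(dim(x))) x <- matrix(x, nrow = length(valid))
  colnames(x) <- object$vars
  eta <- model_eta(object, x)
  raw <- exp(eta - object$lnZmean)
  out <- matrix(NA_real_, grid_nrow(g), grid_ncol(g))
  out[valid] <- if (output == "raw") raw else
    1 - exp(-exp(object$entropy_H) * raw / object$n_background)
  sdm_grid(out, g$origin, g$res, g$crs)
}

# Prediction at point locations (scores used by the evaluation metrics).
predict_points <- function(model, stack, lon, lat,
                           output = c("cloglog", "raw")) {
  output <- match.arg(output)
  grd <- predict.sdm_maxent(model, stack, output = output)
  rc <- cell_index(grd, lon, lat)
  grd$values[rc[, 1] + (rc[, 2] - 1L) * grid_nrow(grd)]
}

#' Permutation importance of each predictor
#'
#' Contribution of a variable is the drop in penalized training gain when its
#' values are permuted across the presence + background training rows
#' (model coefficients fixed), averaged over `n_perm` permutations, floored
#' at zero and normalized to sum to 100.
#'
#' @param model An [fit_maxent()] model.
#' @param stack The training stack.
#' @param seed Integer seed for the permutations.
#' @param n_perm Permutations per variable (default 10).
#' @return Tibble `variable`, `contribution` (percent, sums to 100).
#' @export
percent_contribution <- function(model, stack, seed = 1, n_perm = 10) {
  cells <- c(model$presence_cells, model$background_cells)
  np <- length(model$presence_cells)
  x <- vapply(stack$layers[model$vars], function(l) l$values[cells],
              numeric(length(cells)))
  colnames(x) <- model$vars
  pen <- sum(model$penalty * abs(model$beta))
  gain_of <- function(xm) {
    eta <- model_eta(model, xm)
    mean(eta[seq_len(np)]) - log_mean_exp(eta[-seq_len(np)]) - pen
  }
  g0 <- gain_of(x)
  drops <- with_seed(seed, {
    vapply(model$vars, function(v) {
      mean(vapply(seq_len(n_perm), function(i) {
        xp <- x
        xp[, v] <- xp[sample.int(nrow(xp)), v]
        g0 - gain_of(xp)
      }, numeric(1)))
    }, numeric(1))
  })
  drops <- pmax(drops, 0)
  tot <- sum(drops)
  contribution <- if (tot > 0) 100 * drops / tot else rep(0, length(drops))
  tibble::tibble(variable = model$vars, contribution = contribution)
}

#' Jackknife of variable importance
#'
#' Refits the model excluding each variable in turn (`gain_without`) and with
#' each variable alone (`gain_only`). Gain is the unpenalized training gain
#' `mean_presence(eta) - log mean_background(exp(eta))`, i.e. improvement
#' over the uniform model.
#'
#' @inheritParams fit_maxent
#' @return Tibble `variable`, `gain_without`, `gain_only`, with the
#'   full-model gain in attribute `"full_gain"`.
#' @export
jackknife_gain <- function(presences, background, stack, spec = feature_spec(),
                           rm = 1, maxit = 10000, tol = 1e-7) {
  vars <- names(stack$layers)
  if (length(vars) < 2L) stop("jackknife needs at least 2 variables", call. = FALSE)
  fit_on <- function(keep) {
    sub <- align_stack(stack$layers[keep])
    fit_maxent(presences, background, sub, spec = spec, rm = rm,
               maxit = maxit, tol = tol, on_nonconvergence = "warn")$gain
  }
  full <- fit_maxent(presences, background, stack, spec = spec, rm = rm,
                     maxit = maxit, tol = tol, on_nonconvergence = "warn")$gain
  out <- tibble::tibble(
    variable = vars,
    gain_without = vapply(vars, function(v) fit_on(setdiff(vars, v)), numeric(1)),
    gain_only = vapply(vars, function(v) fit_on(v), numeric(1))
  )
  attr(out, "full_gain") <- full
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the non-zero coefficients of a fitted suitability model
#'
#' @param x An [fit_maxent()] model.
#' @param ... Unused.
#' @return Tibble `feature`, `class`, `var1`, `var2`, `knot`, `estimate`.
#' @export
tidy.sdm_maxent <- function(x, ...) {
  out <- dplyr::mutate(x$meta, estimate = unname(x$beta))
  dplyr::filter(out, .data$estimate != 0)
}

#' One-row model summary
#'
#' @param x An [fit_maxent()] model.
#' @param ... Unused.
#' @return Tibble with feature classes, rm, sample sizes, non-zero feature
#'   count, training gain, entropy, iterations and convergence flag.
#' @export
glance.sdm_maxent <- function(x, ...) {
  tibble::tibble(
    feature_classes = paste(sort(x$spec$classes), collapse = ""),
    rm = x$rm, n_presence = x$m, n_background = x$n_background,
    k_nonzero = sum(x$beta != 0), gain = x$gain, entropy = x$entropy_H,
    iterations = x$iterations, converged = x$converged
  )
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model An [fit_maxent()] model.
#' @param path Output JSON path.
#' @return `path` invisibly; `read_maxent_json()` returns the model.
#' @export
write_maxent_json <- function(model, path) {
  obj <- model[c("beta", "s", "ranges", "rm", "m", "n_background",
                 "lnZmean", "entropy_H", "gain", "penalty", "vars")]
  obj$meta <- model$meta
  obj$spec <- unclass(model$spec)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maxent_json
#' @export
read_maxent_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$meta <- tibble::as_tibble(obj$meta)
  obj$spec <- structure(obj$spec, class = "feature_spec")
  obj$beta <- unlist(obj$beta)
  obj$ranges <- lapply(obj$ranges, unlist)
  structure(obj, class = "sdm_maxent")
}
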