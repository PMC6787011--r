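#' Feature expansion specification
#'
#' Controls how raw predictor values are expanded into model features. All
#' variables are standardized (training mean/sd) before expansion. Classes:
#' `linear` (z), `quadratic` (z^2), `product` (all pairwise z_i z_j) and
#' `hinge` (forward and reverse hinges at training-quantile knots).
#'
#' @param classes Character subset of `c("linear", "quadratic", "product",
#'   "hinge")`; must include `"linear"`.
#' @param n_hinge_knots Number of interior quantile knots per variable.
#' @return An object of class `"feature_spec"`.
#' @export
feature_spec <- function(classes = c("linear", "quadratic"),
                         n_hinge_knots = 8) {
  classes <- match.arg(classes, c("linear", "quadratic", "product", "hinge"),
                       several.ok = TRUE)
  if (!"linear" %in% classes) stop("feature classes must include 'linear'")
  structure(list(classes = classes, n_hinge_knots = as.integer(n_hinge_knots)),
            class = "feature_spec")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# build the feature transform (standardization + knots) from pooled training
# rows, and return a closure that expands a data frame into a design matrix
.make_transform <- function(pooled, spec) {
  vars <- colnames(pooled)
  mu <- vapply(pooled, mean, 0)
  sd <- vapply(pooled, stats::sd, 0)
  sd[!is.finite(sd) | sd == 0] <- 1
  knots <- NULL
  if ("hinge" %in% spec$classes) {
    knots <- lapply(vars, function(v) {
      z <- (pooled[[v]] - mu[[v]]) / sd[[v]]
      qs <- stats::quantile(z, probs = seq_len(spec$n_hinge_knots) /
                              (spec$n_hinge_knots + 1), names = FALSE)
      unique(qs)
    })
    names(knots) <- vars
  }
  expand <- function(df) {
    Z <- vapply(vars, function(v) (df[[v]] - mu[[v]]) / sd[[v]],
                numeric(nrow(df)))
    if (nrow(df) == 1L) Z <- matrix(Z, nrow = 1, dimnames = list(NULL, vars))
    cols <- list()
    for (v in vars) cols[[paste0("lin:", v)]] <- Z[, v]
    if ("quadratic" %in% spec$classes)
      for (v in vars) cols[[paste0("quad:", v)]] <- Z[, v]^2
    if ("product" %in% spec$classes && length(vars) > 1L) {
      cmb <- utils::combn(vars, 2)
      for (i in seq_len(ncol(cmb)))
        cols[[paste0("prod:", cmb[1, i], "*", cmb[2, i])]] <-
          Z[, cmb[1, i]] * Z[, cmb[2, i]]
    }
    if ("hinge" %in% spec$classes) {
      for (v in vars) for (kk in seq_along(knots[[v]])) {
        kv <- knots[[v]][kk]
        cols[[sprintf("hingeF:%s@%d", v, kk)]] <- pmax(Z[, v] - kv, 0)
        cols[[sprintf("hingeR:%s@%d", v, kk)]] <- pmax(kv - Z[, v], 0)
      }
    }
    do.call(cbind, cols)
  }
  list(vars = vars, mu = mu, sd = sd, knots = knots, expand = expand)
}

# negative penalized objective and smooth gradient
.sdm_objective <- function(beta, Zp, Zb, lambda) {
  ep <- drop(Zp %*% beta)
  eb <- drop(Zb %*% beta)
  -sum(ep) + nrow(Zp) * logsumexp(eb) + sum(lambda * abs(beta))
}

#' Fit a presence-background maximum-entropy model
#'
#' Estimates a Gibbs distribution over background cells by maximizing the
#' L1-penalized maximum-entropy log likelihood
#' `sum_presence beta f(x) - n_p log sum_background exp(beta f(x)) -
#' sum_k lambda_k |beta_k|` (the standard MaxEnt objective; equivalently an
#' infinitely-weighted inhomogeneous Poisson point-process likelihood).
#' Optimization is accelerated proximal gradient (FISTA) with backtracking
#' line search and soft-threshold proximal steps; it stops when the objective
#' improves by less than `tol` or after `max_iter` iterations (logged in the
#' returned model). Expanded features that are collinear with earlier ones
#' are pruned before fitting; predictor columns constant across the pooled
#' presence and background rows are dropped with a warning.
#'
#' Per-feature penalties are `reg_lambda` times the feature's pooled-training
#' standard deviation; the default `reg_lambda` is `0.05 sqrt(ln n_p)`.
#'
#' @param presence Data frame of predictor values at presence records.
#' @param background Data frame of predictor values at background cells
#'   (same columns).
#' @param features A [feature_spec()].
#' @param reg_lambda Nonnegative base regularization weight, or `NULL` for
#'   the default.
#' @param seed Integer seed recorded in the metadata (the optimizer itself is
#'   deterministic).
#' @param max_iter,tol Optimizer budget and relative-objective stopping
#'   tolerance.
#' @param meta Optional named list of training metadata (extent, grain, ...).
#' @return An object of class `"sdm_model"`.
#' @export
fit_sdm <- function(presence, background, features = feature_spec(),
                    reg_lambda = NULL, seed = 1, max_iter = 500,
                    tol = 1e-8, meta = list()) {
  presence <- as.data.frame(presence)
  background <- as.data.frame(background)
  if (nrow(presence) < 2L) stop("need at least 2 presence records")
  if (nrow(background) < 2L) stop("need at least 2 background records")
  if (!identical(sort(colnames(presence)), sort(colnames(background))))
    stop("presence and background must share the same variables")
  background <- background[, colnames(presence), drop = FALSE]
  keep <- stats::complete.cases(presence)
  if (!all(keep)) presence <- presence[keep, , drop = FALSE]
  keep <- stats::complete.cases(background)
  if (!all(keep)) background <- background[keep, , drop = FALSE]

  pooled <- rbind(presence, background)
  sds <- vapply(pooled, stats::sd, 0)
  degen <- !is.finite(sds) | sds == 0
  if (all(degen)) stop("all predictors are constant; nothing to fit")
  if (any(degen)) {
    warning("dropping constant predictor(s): ",
            paste(colnames(pooled)[degen], collapse = ", "))
    presence <- presence[, !degen, drop = FALSE]
    background <- background[, !degen, drop = FALSE]
    pooled <- pooled[, !degen, drop = FALSE]
  }

  tr <- .make_transform(pooled, features)
  Zp <- tr$expand(presence)
  Zb <- tr$expand(background)

  # prune collinear expanded features (rank via pivoted QR on pooled rows)
  Zall <- rbind(Zp, Zb)
  qrz <- qr(Zall, tol = 1e-9)
  keep_cols <- sort(qrz$pivot[seq_len(qrz$rank)])
  pruned <- setdiff(colnames(Zall), colnames(Zall)[keep_cols])
  Zp <- Zp[, keep_cols, drop = FALSE]
  Zb <- Zb[, keep_cols, drop = FALSE]

  n_p <- nrow(Zp)
  if (is.null(reg_lambda)) reg_lambda <- 0.05 * sqrt(log(n_p))
  feat_sd <- apply(rbind(Zp, Zb), 2, stats::sd)
  feat_sd[!is.finite(feat_sd) | feat_sd == 0] <- 1
  lambda <- reg_lambda * feat_sd

  grad_g <- function(beta) {
    eb <- drop(Zb %*% beta)
    p <- exp(eb - logsumexp(eb))
    -colSums(Zp) + n_p * drop(crossprod(Zb, p))
  }
  g_val <- function(beta) {
    -sum(Zp %*% beta) + n_p * logsumexp(drop(Zb %*% beta))
  }
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

  p_dim <- ncol(Zp)
  beta <- numeric(p_dim)
  y <- beta
  t_mom <- 1
  step <- 1 / max(n_p, 1)
  obj <- .sdm_objective(beta, Zp, Zb, lambda)
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iters <- it
    gy <- g_val(y)
    gr <- grad_g(y)
    repeat {
      cand <- soft(y - step * gr, step * lambda)
      dlt <- cand - y
      if (g_val(cand) <= gy + sum(gr * dlt) + sum(dlt^2) / (2 * step) + 1e-12)
        break
      step <- step / 2
      if (step < 1e-18) break
    }
    obj_new <- .sdm_objective(cand, Zp, Zb, lambda)
    if (obj_new > obj) {          # restart momentum from the last iterate
      y <- beta
      t_mom <- 1
      next
    }
    t_new <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
    y <- cand + ((t_mom - 1) / t_new) * (cand - beta)
    beta_prev <- beta
    beta <- cand
    t_mom <- t_new
    step <- step * 1.5            # allow the step to grow back
    if (abs(obj - obj_new) < tol * (abs(obj) + 1)) {
      obj <- obj_new
      converged <- TRUE
      break
    }
    obj <- obj_new
  }
  names(beta) <- colnames(Zp)

  eb <- drop(Zb %*% beta)
  log_alpha <- logsumexp(eb)
  pbg <- exp(eb - log_alpha)
  entropy <- -sum(pbg * log(pmax(pbg, 1e-300)))

  var_stats <- data.frame(
    variable = tr$vars,
    mean = vapply(tr$vars, function(v) mean(pooled[[v]]), 0),
    min = vapply(tr$vars, function(v) min(pooled[[v]]), 0),
    max = vapply(tr$vars, function(v) max(pooled[[v]]), 0),
    row.names = NULL
  )

  structure(list(
    features = features, transform = tr, beta = beta,
    feature_names = colnames(Zp), pruned = pruned,
    lambda = lambda, reg_lambda = reg_lambda,
    log_alpha = log_alpha, entropy = entropy,
    n_presence = n_p, n_background = nrow(Zb),
    var_stats = var_stats,
    convergence = list(iterations = iters, converged = converged,
                       objective = obj),
    seed = seed, meta = meta
  ), class = "sdm_model")
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("<sdm_model> %d presences vs %d background cells\n",
              x$n_presence, x$n_background))
  cat(sprintf("  features: %s (%d terms, %d nonzero)\n",
              paste(x$features$classes, collapse = "+"),
              length(x$beta), sum(x$beta != 0)))
  cat(sprintf("  reg_lambda %.4g; %s after %d iterations (objective %.6g)\n",
              x$reg_lambda,
              if (x$convergence$converged) "converged" else "iteration cap hit",
              x$convergence$iterations, x$convergence$objective))
  invisible(x)
}

# linear predictor beta . f(x) for a data frame of raw variable values
.sdm_eta <- function(model, newdata) {
  Z <- model$transform$expand(as.data.frame(newdata))
  Z <- Z[, model$feature_names, drop = FALSE]
  drop(Z %*% model$beta)
}

#' Predict suitability from a fitted model
#'
#' `raw` is the Gibbs density `exp(beta f(x)) / alpha`, normalized so it sums
#' to 1 over the training background; `cloglog` is the bounded suitability
#' scale `1 - exp(-exp(H + log raw))`, with `H` the entropy of the training
#' background distribution. Ranks are identical on both scales. Rows with
#' missing predictors (or nodata cells of a stack) propagate `NA`.
#'
#' @param object A fitted [fit_sdm()] model.
#' @param newdata Data frame of predictor values, or a [predictor_stack()]
#'   containing all model variables (then a [raster_grid()] is returned).
#' @param scale `"cloglog"` (default) or `"raw"`.
#' @param ... Unused.
#' @return Numeric vector, or a [raster_grid()] when `newdata` is a stack.
#' @export
predict.sdm_model <- function(object, newdata, scale = c("cloglog", "raw"),
                              ...) {
  scale <- match.arg(scale)
  if (inherits(newdata, "predictor_stack")) {
    miss <- setdiff(object$transform$vars, names(newdata$layers))
    if (length(miss) > 0L)
      stop("stack is missing model variable(s): ", paste(miss, collapse = ", "))
    tmpl <- newdata$layers[[1]]
    df <- as.data.frame(lapply(newdata$layers[object$transform$vars],
                               function(r) as.vector(r$values)))
    ok <- stats::complete.cases(df)
    out <- rep(NA_real_, nrow(df))
    if (any(ok))
      out[ok] <- predict(object, df[ok, , drop = FALSE], scale = scale)
    return(raster_grid(matrix(out, nrow(tmpl$values), ncol(tmpl$values)),
                       tmpl$x0, tmpl$y0, tmpl$cell, tmpl$nodata))
  }
  df <- as.data.frame(newdata)
  miss <- setdiff(object$transform$vars, colnames(df))
  if (length(miss) > 0L)
    stop("newdata is missing model variable(s): ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(df[, object$transform$vars, drop = FALSE])
  out <- rep(NA_real_, nrow(df))
  if (!any(ok)) return(out)
  eta <- .sdm_eta(object, df[ok, , drop = FALSE])
  lraw <- eta - object$log_alpha
  out[ok] <- if (scale == "raw") exp(lraw)
  else 1 - exp(-exp(object$entropy + lraw))
  out
}

#' Permutation importance of model variables
#'
#' For each variable, permutes its values jointly across the pooled training
#' presence and background rows (seeded), recomputes the training AUC, and
#' records the drop `max(0, AUC_orig - AUC_perm)`. Drops are normalized to
#' sum to 100; if every drop is zero, equal shares are returned.
#'
#' @param model A fitted [fit_sdm()] model.
#' @param presence,background Training data frames used for the fit.
#' @param seed Integer seed for the permutations.
#' @return Named numeric vector of percentages summing to 100.
#' @export
permutation_importance <- function(model, presence, background, seed = 1) {
  presence <- as.data.frame(presence)[, model$transform$vars, drop = FALSE]
  background <- as.data.frame(background)[, model$transform$vars, drop = FALSE]
  pooled <- rbind(presence, background)
  n_p <- nrow(presence)
  eta <- .sdm_eta(model, pooled)
  auc0 <- auc(eta[seq_len(n_p)], eta[-seq_len(n_p)])
  drops <- vapply(seq_along(model$transform$vars), function(j) {
    v <- model$transform$vars[j]
    perm <- withr::with_seed(derive_seed(seed, "perm_importance", v),
                             sample(nrow(pooled)))
    shuffled <- pooled
    shuffled[[v]] <- pooled[[v]][perm]
    eta_p <- .sdm_eta(model, shuffled)
    max(0, auc0 - auc(eta_p[seq_len(n_p)], eta_p[-seq_len(n_p)]))
  }, 0)
  names(drops) <- model$transform$vars
  if (sum(drops) > 0) 100 * drops / sum(drops)
  else stats::setNames(rep(100 / length(drops), length(drops)), names(drops))
}

#' Response curve of one variable
#'
#' Evaluates the cloglog prediction along `n` equally spaced values spanning
#' the variable's observed training range, holding every other variable at
#' its training mean.
#'
#' @param model A fitted [fit_sdm()] model.
#' @param variable Variable name.
#' @param n Number of evaluation points (default 100).
#' @return Data frame with columns `value` and `suitability`.
#' @export
response_curve <- function(model, variable, n = 100) {
  vs <- model$var_stats
  if (!variable %in% vs$variable)
    stop("unknown model variable: ", variable)
  row <- vs[vs$variable == variable, ]
  grid <- seq(row$min, row$max, length.out = n)
  df <- as.data.frame(lapply(stats::setNames(vs$mean, vs$variable),
                             rep, times = n))
  df[[variable]] <- grid
  data.frame(value = grid,
             suitability = predict(model, df, scale = "cloglog"))
}

#' Presence-only AICc of a fitted model
#'
#' Uses the normalized-likelihood convention for presence-background models:
#' the model's raw density is renormalized over the supplied background (or
#' landscape) cells, the log likelihood is the sum of the normalized log
#' densities at the presence records, `K` is the number of nonzero
#' coefficients, and `AICc = 2K - 2LL + 2K(K+1)/(n - K - 1)` with `n` the
#' number of presences. Returns `NA` (not computable) when `n <= K + 1`.
#'
#' @param model A fitted [fit_sdm()] model.
#' @param presence Data frame of predictor values at presence records.
#' @param background Data frame of predictor values at the normalization
#'   cells (typically all landscape/background cells of the extent).
#' @return AICc as a single number, or `NA_real_` when undefined.
#' @export
aicc_sdm <- function(model, presence, background) {
  K <- sum(model$beta != 0)
  n <- nrow(as.data.frame(presence))
  if (n <= K + 1) return(NA_real_)
  eta_p <- .sdm_eta(model, presence)
  eta_b <- .sdm_eta(model, background)
  ll <- sum(eta_p - logsumexp(eta_b))
  2 * K - 2 * ll + 2 * K * (K + 1) / (n - K - 1)
}

#' Serialize a fitted model to JSON
#'
#' @param model A fitted [fit_sdm()] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sdm_json <- function(model, path) {
  tr <- model$transform
  rec <- list(
    classes = model$features$classes,
    n_hinge_knots = model$features$n_hinge_knots,
    variables = tr$vars,
    standardization = list(mean = as.list(tr$mu), sd = as.list(tr$sd)),
    knots = tr$knots,
    beta = as.list(model$beta),
    log_alpha = model$log_alpha,
    entropy = model$entropy,
    reg_lambda = model$reg_lambda,
    n_presence = model$n_presence,
    n_background = model$n_background,
    convergence = model$convergence,
    meta = model$meta
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
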