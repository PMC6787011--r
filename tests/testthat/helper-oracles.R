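# Independent brute-force oracles used to check the package implementations.

# AUC by exhaustive pair counting
oracle_auc <- function(pres, bg) {
  conc <- 0
  for (p in pres) for (b in bg)
    conc <- conc + if (p > b) 1 else if (p == b) 0.5 else 0
  conc / (length(pres) * length(bg))
}

# max TSS by exhaustive threshold enumeration
oracle_max_tss <- function(pres, bg) {
  thr <- sort(unique(c(pres, bg)))
  best <- -Inf; best_t <- NA_real_
  for (t in thr) {
    tss <- mean(pres >= t) + mean(bg < t) - 1
    if (tss > best) { best <- tss; best_t <- t }
  }
  list(tss = best, threshold = best_t)
}

# direct numerical maximization of the penalized maximum-entropy objective,
# exact L1 handling via the beta = beta+ - beta- nonnegative splitting
oracle_fit_beta <- function(Zp, Zb, lambda) {
  p <- ncol(Zp)
  np <- nrow(Zp)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  obj <- function(bpm) {
    b <- bpm[1:p] - bpm[(p + 1):(2 * p)]
    -sum(Zp %*% b) + np * lse(drop(Zb %*% b)) +
      sum(lambda * (bpm[1:p] + bpm[(p + 1):(2 * p)]))
  }
  grad <- function(bpm) {
    b <- bpm[1:p] - bpm[(p + 1):(2 * p)]
    eb <- drop(Zb %*% b)
    w <- exp(eb - lse(eb))
    g <- -colSums(Zp) + np * drop(crossprod(Zb, w))
    c(g + lambda, -g + lambda)
  }
  o <- stats::optim(rep(0, 2 * p), obj, grad, method = "L-BFGS-B", lower = 0,
                    control = list(maxit = 2000, factr = 1e3))
  o$par[1:p] - o$par[(p + 1):(2 * p)]
}

# Gibbs cell probabilities over the background rows for a coefficient vector
gibbs_probs <- function(Zb, beta) {
  e <- drop(Zb %*% beta)
  e <- e - max(e)
  exp(e) / sum(exp(e))
}

# Horn slope at the center of a 3x3 elevation patch, in degrees
oracle_horn_center <- function(m, cell) {
  dzdx <- ((m[1, 3] + 2 * m[2, 3] + m[3, 3]) -
             (m[1, 1] + 2 * m[2, 1] + m[3, 1])) / (8 * cell)
  dzdy <- ((m[3, 1] + 2 * m[3, 2] + m[3, 3]) -
             (m[1, 1] + 2 * m[1, 2] + m[1, 3])) / (8 * cell)
  atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
}
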