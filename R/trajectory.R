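## Trajectory-level activation-efficiency statistics from per-frame labels,
## confidences and nucleophilic-attack distances.

#' Construct a per-frame label series
#'
#' @param labels binary vector (1 reactive, 0 nonreactive); logicals and
#'   the strings "reactive"/"nonreactive" are accepted.
#' @param confidences optional per-frame confidences in `[0.5, 1]`.
#' @param frames optional frame ids (default `1:n`).
#' @return a data.frame of class `label_series` with columns `frame`,
#'   `label` and, when given, `confidence`.
#' @export
label_series <- function(labels, confidences = NULL, frames = NULL) {
  if (is.character(labels)) labels <- as.integer(labels == "reactive")
  if (is.logical(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (length(labels) && !all(labels %in% c(0L, 1L)))
    stop_lapnet("labels must be binary (0/1)", class = "lapnet_validation")
  frames <- if (is.null(frames)) seq_along(labels) else frames
  if (length(frames) != length(labels))
    stop_lapnet("frames and labels must have equal length",
                class = "lapnet_validation")
  out <- data.frame(frame = frames, label = labels)
  if (!is.null(confidences)) {
    if (length(confidences) != length(labels))
      stop_lapnet("confidences and labels must have equal length",
                  class = "lapnet_validation")
    if (any(confidences < 0.5 - 1e-9 | confidences > 1 + 1e-9, na.rm = TRUE))
      stop_lapnet("confidences must lie in [0.5, 1]", class = "lapnet_validation")
    out$confidence <- confidences
  }
  class(out) <- c("label_series", "data.frame")
  out
}

as_label_series <- function(x) {
  if (inherits(x, "label_series")) return(x)
  if (is.data.frame(x)) {
    return(label_series(x$label, x$confidence, x$frame))
  }
  label_series(x)
}

#' Reactive fraction (activation efficiency) of a label series
#'
#' The mean of the per-frame binary labels: the proportion of trajectory
#' frames in which the carbonyl carbon is activated.
#'
#' @param series a `label_series` (or plain binary vector).
#' @return fraction in `[0, 1]`.
#' @export
reactive_fraction <- function(series) {
  s <- as_label_series(series)
  if (nrow(s) == 0L)
    stop_lapnet("empty label series", class = "lapnet_contract")
  mean(s$label)
}

#' Maximal-run decomposition of a label series
#'
#' @param series a `label_series` (or plain binary vector).
#' @return list with `reactive` and `nonreactive` run-length vectors; the
#'   lengths partition the series (they sum to its length).
#' @export
run_lengths <- function(series) {
  s <- as_label_series(series)
  if (nrow(s) == 0L)
    stop_lapnet("empty label series", class = "lapnet_contract")
  r <- rle(s$label)
  list(reactive = r$lengths[r$values == 1L],
       nonreactive = r$lengths[r$values == 0L])
}

# exact conditional null pmf of the number of runs R given n1 ones and n0
# zeros: P(R = 2k)   = 2 C(n1-1,k-1) C(n0-1,k-1) / C(n,n1)
#        P(R = 2k+1) = [C(n1-1,k) C(n0-1,k-1) + C(n1-1,k-1) C(n0-1,k)] / C(n,n1)
runs_null_pmf <- function(n1, n0) {
  n <- n1 + n0
  r <- 2:(2 * min(n1, n0) + (n1 != n0))
  lden <- lchoose(n, n1)
  p <- vapply(r, function(ri) {
    if (ri %% 2 == 0) {
      k <- ri / 2
      exp(log(2) + lchoose(n1 - 1, k - 1) + lchoose(n0 - 1, k - 1) - lden)
    } else {
      k <- (ri - 1) / 2
      exp(lchoose(n1 - 1, k) + lchoose(n0 - 1, k - 1) - lden) +
        exp(lchoose(n1 - 1, k - 1) + lchoose(n0 - 1, k) - lden)
    }
  }, numeric(1))
  data.frame(runs = r, prob = p)
}

#' Wald-Wolfowitz runs test of label-sequence randomness
#'
#' Tests the observed number of maximal runs against the i.i.d. null
#' conditioned on the state counts. For series up to `exact_max` frames the
#' exact conditional distribution is used with a minimum-likelihood
#' two-sided p-value (the sum of run counts no more probable than the
#' observed one); longer series use the normal approximation with
#' continuity correction.
#'
#' @param series a `label_series` (or plain binary vector) containing both
#'   states.
#' @param level significance level for the verdict (default 0.05).
#' @param exact_max largest series length for the exact null (default 200).
#' @return list of class `runs_test` with `statistic` (observed runs),
#'   `expected`, `p.value`, `method` and `verdict` (`"random"` when the
#'   null of random alternation is not rejected, `"nonrandom"` otherwise).
#' @export
runs_test <- function(series, level = 0.05, exact_max = 200) {
  s <- as_label_series(series)
  n1 <- sum(s$label == 1L); n0 <- sum(s$label == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_lapnet("runs test undefined: series contains a single state",
                class = "lapnet_contract")
  n <- n1 + n0
  robs <- length(rle(s$label)$lengths)
  mu <- 1 + 2 * n1 * n0 / n
  if (n <= exact_max) {
    pmf <- runs_null_pmf(n1, n0)
    p_obs <- pmf$prob[pmf$runs == robs]
    pval <- sum(pmf$prob[pmf$prob <= p_obs * (1 + 1e-9)])
    method <- "exact conditional"
  } else {
    sig2 <- 2 * n1 * n0 * (2 * n1 * n0 - n) / (n^2 * (n - 1))
    z <- (robs - mu)
    z <- (abs(z) - 0.5) / sqrt(sig2)      # continuity-corrected
    pval <- 2 * stats::pnorm(-max(z, 0))
    method <- "normal approximation"
  }
  pval <- min(1, pval)
  structure(list(statistic = robs, expected = mu, p.value = pval,
                 n_reactive = n1, n_nonreactive = n0, level = level,
                 method = method,
                 verdict = if (pval < level) "nonrandom" else "random"),
            class = "runs_test")
}

#' @export
print.runs_test <- function(x, ...) {
  cat("Wald-Wolfowitz runs test (", x$method, ")\n", sep = "")
  cat("  runs =", x$statistic, " expected =", signif(x$expected, 4),
      " p =", signif(x$p.value, 4), "->", x$verdict, "\n")
  invisible(x)
}

#' Per-class confidence summaries of a label series
#'
#' @param series a `label_series` with confidences.
#' @return list of class `confidence_summary` with a `summary` data.frame
#'   (per predicted class: n, mean, median, quantiles) and `values` (raw
#'   per-frame export for violin-style plots).
#' @export
confidence_summary <- function(series) {
  s <- as_label_series(series)
  if (is.null(s$confidence))
    stop_lapnet("label series carries no confidences", class = "lapnet_contract")
  cls <- ifelse(s$label == 1L, "reactive", "nonreactive")
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  rows <- lapply(unique(cls), function(cl) {
    v <- s$confidence[cls == cl]
    q <- stats::quantile(v, qs, names = FALSE)
    data.frame(class = cl, n = length(v), mean = mean(v),
               q05 = q[1], q25 = q[2], median = q[3], q75 = q[4], q95 = q[5])
  })
  structure(list(summary = do.call(rbind, rows),
                 values = data.frame(frame = s$frame, class = cls,
                                     confidence = s$confidence)),
            class = "confidence_summary")
}

## ---- 1-D Gaussian mixture fitting (EM) --------------------------------

row_max <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmax(out, m[, j])
  out
}

component_loglik <- function(x, w, mu, sd) {
  k <- length(w)
  lcomp <- matrix(0, length(x), k)
  for (j in seq_len(k))
    lcomp[, j] <- log(w[j]) + stats::dnorm(x, mu[j], sd[j], log = TRUE)
  lcomp
}

mixture_loglik <- function(x, w, mu, sd) {
  lcomp <- component_loglik(x, w, mu, sd)
  m <- row_max(lcomp)
  sum(m + log(rowSums(exp(lcomp - m))))
}

em_once <- function(x, k, mu0, max_iter, tol, sd_floor) {
  n <- length(x)
  w <- rep(1 / k, k)
  mu <- mu0
  sd <- rep(stats::sd(x), k)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  pruned <- FALSE
  for (iter in seq_len(max_iter)) {
    lcomp <- component_loglik(x, w, mu, sd)
    m <- row_max(lcomp)
    lse <- m + log(rowSums(exp(lcomp - m)))
    r <- exp(lcomp - lse)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sd <- sqrt(colSums(r * (outer(x, mu, "-")^2)) / nk)
    bad <- !is.finite(sd) | sd < sd_floor | !is.finite(mu) | w < 1e-10
    if (any(bad)) {
      # degenerate collapse: prune the component(s) and continue smaller
      pruned <- TRUE
      keep <- which(!bad)
      if (length(keep) == 0L) break
      k <- length(keep)
      w <- w[keep] / sum(w[keep]); mu <- mu[keep]; sd <- sd[keep]
    }
  }
  ord <- order(mu)
  list(k = k, weights = w[ord], means = mu[ord], sds = sd[ord],
       loglik = trace[length(trace)], trace = trace,
       converged = converged, pruned = pruned)
}

#' Fit a k-component normal mixture to attack distances by EM
#'
#' Expectation-maximization for a one-dimensional Gaussian mixture with
#' multiple seeded restarts; the fit with the best log-likelihood is kept.
#' The per-iteration log-likelihood trace is returned and is non-decreasing
#' up to the convergence tolerance. Components collapsing to zero variance
#' are pruned and flagged. Components are reported sorted by mean.
#'
#' @param distances numeric vector of nucleophilic-attack distances
#'   (angstrom); needs `length(distances) > 10 * k`.
#' @param k number of components (the attack-distance distributions of
#'   flexible complexes need at least three).
#' @param seed RNG seed for the restarts.
#' @param restarts number of random restarts (default 10).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return list of class `mixture_fit` with `k`, `weights`, `means`, `sds`,
#'   `loglik`, `trace`, `converged`, `pruned`.
#' @export
fit_distance_mixture <- function(distances, k = 3, seed = 1, restarts = 10,
                                 max_iter = 500, tol = 1e-8) {
  x <- as.numeric(distances)
  x <- x[is.finite(x)]
  if (length(x) <= 10 * k)
    stop_lapnet("need more than 10*k observations to fit a ", k,
                "-component mixture", class = "lapnet_contract")
  if (k == 1) {
    mu <- mean(x); sd <- sqrt(mean((x - mu)^2))
    ll <- mixture_loglik(x, 1, mu, sd)
    return(structure(list(k = 1L, weights = 1, means = mu, sds = sd,
                          loglik = ll, trace = ll, converged = TRUE,
                          pruned = FALSE),
                     class = "mixture_fit"))
  }
  set.seed(seed)
  sd_floor <- 1e-6 * stats::sd(x)
  best <- NULL
  for (r in seq_len(restarts)) {
    mu0 <- sort(sample(x, k))
    fit <- em_once(x, k, mu0, max_iter, tol, sd_floor)
    if (is.null(best) || (is.finite(fit$loglik) && fit$loglik > best$loglik))
      best <- fit
  }
  structure(best, class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("normal mixture fit, k =", x$k,
      if (x$pruned) "(pruned)" else "", "\n")
  print(data.frame(weight = round(x$weights, 4), mean = round(x$means, 4),
                   sd = round(x$sds, 4)))
  cat("  log-likelihood:", x$loglik, " converged:", x$converged, "\n")
  invisible(x)
}

#' BIC over candidate component counts
#'
#' Reports the Bayesian information criterion of mixture fits over a range
#' of k, as guidance; no automatic selection is imposed.
#'
#' @param distances numeric distance vector.
#' @param k_values candidate component counts.
#' @param ... passed to [fit_distance_mixture()].
#' @return data.frame with columns `k`, `loglik`, `bic`.
#' @export
mixture_bic <- function(distances, k_values = 1:4, ...) {
  n <- length(distances)
  rows <- lapply(k_values, function(k) {
    fit <- fit_distance_mixture(distances, k = k, ...)
    npar <- 3 * fit$k - 1
    data.frame(k = k, k_effective = fit$k, loglik = fit$loglik,
               bic = -2 * fit$loglik + npar * log(n))
  })
  do.call(rbind, rows)
}

## ---- CSV interfaces ---------------------------------------------------

#' Read a label series from CSV
#'
#' Expects columns `frame`, `label` and optionally `confidence`.
#' @param path CSV path.
#' @return a `label_series`.
#' @export
read_label_series <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("frame", "label") %in% names(df)))
    stop_lapnet("label CSV needs columns frame, label", class = "lapnet_io")
  label_series(df$label, df$confidence, df$frame)
}

#' Write a label series to CSV
#' @param series a `label_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read a distance series from CSV (columns `frame`, `distance`)
#' @param path CSV path.
#' @return data.frame with `frame`, `distance`.
#' @export
read_distance_series <- function(path) {
  df <- utils::read.csv(path)
  if (!"distance" %in% names(df))
    stop_lapnet("distance CSV needs a 'distance' column", class = "lapnet_io")
  df
}

#' Full trajectory report
#'
#' Bundles the reactive fraction, run-length decomposition, randomness
#' test, confidence summaries (when available) and optionally a distance
#' mixture fit into one report list, ready for JSON export.
#'
#' @param series a `label_series`.
#' @param distances optional distance vector.
#' @param k mixture components for `distances`.
#' @param seed RNG seed for the mixture restarts.
#' @return list of class `trajectory_report`.
#' @export
trajectory_report <- function(series, distances = NULL, k = 3, seed = 1) {
  s <- as_label_series(series)
  runs <- run_lengths(s)
  rep <- list(n_frames = nrow(s),
              reactive_fraction = reactive_fraction(s),
              run_lengths = runs,
              mean_run_reactive = if (length(runs$reactive)) mean(runs$reactive) else NA,
              mean_run_nonreactive = if (length(runs$nonreactive)) mean(runs$nonreactive) else NA)
  if (length(unique(s$label)) == 2L) {
    rt <- runs_test(s)
    rep$runs_test <- list(runs = rt$statistic, expected = rt$expected,
                          p_value = rt$p.value, verdict = rt$verdict)
  }
  if (!is.null(s$confidence))
    rep$confidence <- confidence_summary(s)$summary
  if (!is.null(distances)) {
    fit <- fit_distance_mixture(distances, k = k, seed = seed)
    rep$distance_mixture <- list(k = fit$k, weights = fit$weights,
                                 means = fit$means, sds = fit$sds,
                                 loglik = fit$loglik, converged = fit$converged)
  }
  structure(rep, class = "trajectory_report")
}
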