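#' Build a paired expression profile for one subject
#'
#' Restricts the case and control vectors to their shared gene identifiers
#' and computes per-gene log2 fold changes. Linear-scale input is shifted
#' by a pseudocount and log2-transformed; log2-scale input is used as-is.
#'
#' @param case,control Named numeric vectors of expression values (names
#'   are gene ids).
#' @param input_scale `"log2"` (default) or `"linear"`.
#' @param pseudocount Added to linear-scale values before the log transform
#'   (default 1). Ignored for log2 input.
#' @return Object of class `paired_profile`: list with `gene_ids`,
#'   `expr_case`, `expr_control`, `log2fc`, `abs_log2fc`.
#' @export
make_paired_profile <- function(case, control,
                                input_scale = c("log2", "linear"),
                                pseudocount = 1) {
  input_scale <- match.arg(input_scale)
  if (is.null(names(case)) || is.null(names(control)))
    stop("case and control must be named by gene id")
  if (anyDuplicated(names(case)) || anyDuplicated(names(control)))
    stop("gene ids must be unique within each vector")
  shared <- intersect(names(case), names(control))
  if (length(shared) == 0L) stop("no shared gene identifiers")
  x <- as.numeric(case[shared])
  y <- as.numeric(control[shared])
  if (input_scale == "linear") {
    x <- x + pseudocount
    y <- y + pseudocount
    if (any(x <= 0) || any(y <= 0))
      stop("nonpositive linear values after pseudocount ", pseudocount)
    x <- log2(x)
    y <- log2(y)
  }
  lfc <- x - y
  structure(list(gene_ids = shared, expr_case = x, expr_control = y,
                 log2fc = lfc, abs_log2fc = abs(lfc)),
            class = "paired_profile")
}

#' @export
print.paired_profile <- function(x, ...) {
  cat("paired_profile:", length(x$gene_ids), "genes; |log2FC| median",
      signif(stats::median(x$abs_log2fc), 3), "\n")
  invisible(x)
}

SIGMA_FLOOR <- 1e-3   # sqrt of the 1e-6 variance floor
PI_EPS <- 1e-6

# one EM run from a given start; x is the |log2FC| vector
em_run <- function(x, start, max_iter, tol) {
  pi_a <- min(max(start$pi, PI_EPS), 1 - PI_EPS)
  mu_u <- start$mu_u; mu_a <- start$mu_a
  s_u <- max(start$s_u, SIGMA_FLOOR); s_a <- max(start$s_a, SIGMA_FLOOR)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  clamped <- FALSE
  for (it in seq_len(max_iter)) {
    la <- log(pi_a) + stats::dnorm(x, mu_a, s_a, log = TRUE)
    lu <- log1p(-pi_a) + stats::dnorm(x, mu_u, s_u, log = TRUE)
    m <- pmax(la, lu)
    denom <- m + log(exp(la - m) + exp(lu - m))
    r <- exp(la - denom)                 # P(altered | x)
    ll <- sum(denom)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll

    sa <- sum(r)
    su <- sum(1 - r)
    pi_a <- min(max(sa / length(x), PI_EPS), 1 - PI_EPS)
    mu_a <- sum(r * x) / max(sa, 1e-12)
    mu_u <- sum((1 - r) * x) / max(su, 1e-12)
    v_a <- sum(r * (x - mu_a)^2) / max(sa, 1e-12)
    v_u <- sum((1 - r) * (x - mu_u)^2) / max(su, 1e-12)
    if (v_a < SIGMA_FLOOR^2 || v_u < SIGMA_FLOOR^2) clamped <- TRUE
    s_a <- sqrt(max(v_a, SIGMA_FLOOR^2))
    s_u <- sqrt(max(v_u, SIGMA_FLOOR^2))
  }
  list(pi_a = pi_a, mu_u = mu_u, mu_a = mu_a, s_u = s_u, s_a = s_a,
       loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
       n_iter = length(ll_trace), converged = converged, clamped = clamped)
}

#' Fit the two-component Gaussian mixture to absolute fold changes
#'
#' Models the `|log2FC|` values of one paired profile as a mixture of an
#' "unaltered" component (small fold changes) and an "altered" component
#' (large fold changes), fit by expectation-maximisation. The first start
#' is deterministic (unaltered mean at the median, altered mean at the 95th
#' percentile, pooled SD for both, mixing proportion 0.1); the remaining
#' `n_starts - 1` starts are seeded random perturbations of it. The fit
#' with the best log-likelihood is returned, components relabelled so that
#' `mu_unaltered <= mu_altered`.
#'
#' @param values Nonnegative numeric vector (typically `abs_log2fc`),
#'   length at least 50 and not all identical.
#' @param max_iter Maximum EM iterations per start (default 1000).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param n_starts Number of EM starts (default 5).
#' @param seed Integer seed for the random restarts.
#' @return Object of class `mixture_fit`: list with `pi_altered`,
#'   `mu_unaltered`, `mu_altered`, `sigma_unaltered`, `sigma_altered`,
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`.
#' @export
fit_mixture <- function(values, max_iter = 1000L, tol = 1e-8,
                        n_starts = 5L, seed = 1L) {
  x <- as.numeric(values)
  if (any(!is.finite(x)) || any(x < 0))
    stop("values must be finite and nonnegative")
  if (length(x) < 50L) stop("need at least 50 values to fit the mixture")
  if (stats::sd(x) == 0) stop("all values identical; mixture undefined")

  base <- list(pi = 0.1,
               mu_u = stats::median(x),
               mu_a = stats::quantile(x, 0.95, names = FALSE),
               s_u = stats::sd(x), s_a = stats::sd(x))
  if (base$mu_a <= base$mu_u) base$mu_a <- base$mu_u + stats::sd(x)

  starts <- list(base)
  if (n_starts > 1L) {
    if (!is.null(seed)) set.seed(seed)
    for (k in seq_len(n_starts - 1L)) {
      starts[[k + 1L]] <- list(
        pi = min(max(base$pi * exp(stats::rnorm(1, 0, 0.5)), 0.01), 0.5),
        mu_u = base$mu_u * stats::runif(1, 0.5, 1.5),
        mu_a = base$mu_a * stats::runif(1, 0.6, 1.6),
        s_u = base$s_u * stats::runif(1, 0.5, 1.5),
        s_a = base$s_a * stats::runif(1, 0.5, 1.5))
    }
  }
  runs <- lapply(starts, function(st) em_run(x, st, max_iter, tol))
  best <- runs[[which.max(vapply(runs, `[[`, 0, "loglik"))]]
  if (best$clamped)
    warning("fit_mixture: component variance clamped at floor")

  # relabel so the unaltered component has the smaller mean
  if (best$mu_a < best$mu_u) {
    best[c("mu_u", "mu_a")] <- best[c("mu_a", "mu_u")]
    best[c("s_u", "s_a")] <- best[c("s_a", "s_u")]
    best$pi_a <- 1 - best$pi_a
  }
  structure(list(pi_altered = best$pi_a,
                 mu_unaltered = best$mu_u, mu_altered = best$mu_a,
                 sigma_unaltered = best$s_u, sigma_altered = best$s_a,
                 loglik = best$loglik, loglik_trace = best$ll_trace,
                 n_iter = best$n_iter, converged = best$converged),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "mixture_fit: pi_altered=%.4f  unaltered N(%.3f, %.3f)  altered N(%.3f, %.3f)\n",
    x$pi_altered, x$mu_unaltered, x$sigma_unaltered,
    x$mu_altered, x$sigma_altered))
  cat(sprintf("  loglik=%.3f after %d iteration(s); converged: %s\n",
              x$loglik, x$n_iter, x$converged))
  invisible(x)
}

#' Posterior probability of the altered component
#'
#' Computes `P(altered | x)` for each value under a fitted mixture, in
#' log-space to avoid underflow.
#'
#' @param fit A `mixture_fit`.
#' @param values Numeric vector of `|log2FC|` values.
#' @return Numeric vector of posteriors in `[0, 1]`.
#' @export
posterior_altered <- function(fit, values) {
  x <- as.numeric(values)
  la <- log(fit$pi_altered) +
    stats::dnorm(x, fit$mu_altered, fit$sigma_altered, log = TRUE)
  lu <- log1p(-fit$pi_altered) +
    stats::dnorm(x, fit$mu_unaltered, fit$sigma_unaltered, log = TRUE)
  m <- pmax(la, lu)
  exp(la - (m + log(exp(la - m) + exp(lu - m))))
}

#' Does a fitted mixture show a genuine altered component?
#'
#' Guards against arbitrary splits of unimodal noise: when the separation
#' between the component means is less than `guard` times the unaltered
#' component's standard deviation, the fit is declared signal-free and no
#' genes should be called altered.
#'
#' @param fit A `mixture_fit`.
#' @param guard Separation multiplier (default 0.5).
#' @return Logical.
#' @export
has_signal <- function(fit, guard = 0.5) {
  (fit$mu_altered - fit$mu_unaltered) >= guard * fit$sigma_unaltered
}

#' Call differentially expressed genes from mixture posteriors
#'
#' A gene is called a DEG when its posterior probability of the altered
#' component strictly exceeds `deg_threshold`. The expression direction is
#' the sign of its log2 fold change (`"zero"` only at exactly 0). When a
#' `fit` is supplied and fails the no-signal guard ([has_signal()]), every
#' gene is left uncalled.
#'
#' @param profile A `paired_profile`.
#' @param posteriors Numeric vector aligned with `profile$gene_ids`.
#' @param deg_threshold Posterior cutoff, strict (default 0.5).
#' @param fit Optional `mixture_fit` used for the no-signal guard.
#' @param signal_guard Guard multiplier passed to [has_signal()].
#' @return data.frame with columns `gene_id`, `log2fc`, `posterior_altered`,
#'   `is_deg`, `direction`.
#' @export
call_degs <- function(profile, posteriors, deg_threshold = 0.5,
                      fit = NULL, signal_guard = 0.5) {
  if (length(posteriors) != length(profile$gene_ids))
    stop("posteriors not aligned with profile genes")
  is_deg <- posteriors > deg_threshold
  if (!is.null(fit) && !has_signal(fit, signal_guard))
    is_deg[] <- FALSE
  direction <- ifelse(profile$log2fc > 0, "up",
                      ifelse(profile$log2fc < 0, "down", "zero"))
  data.frame(gene_id = profile$gene_ids,
             log2fc = profile$log2fc,
             posterior_altered = posteriors,
             is_deg = is_deg,
             direction = direction,
             stringsAsFactors = FALSE)
}
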