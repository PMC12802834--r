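# Same-chromosome exclusion filter and mixture-based Ks peak counting.

#' Keep only inter-chromosomal paralog pairs
#'
#' Paralog pairs whose two genes lie on the same chromosome are excluded
#' before Ks analysis: recent tandem duplicates sit next to each other and
#' would flood the low-Ks range, whereas WGD-derived pairs start out on
#' distinct chromosome copies.
#'
#' @param pairs Tibble with columns gene_a, gene_b.
#' @param genes Gene table with columns gene_id, chromosome (all pair members
#'   must be present).
#' @return The subset of `pairs` on different chromosomes, with
#'   `interchromosomal = TRUE` set.
#' @export
filter_interchromosomal <- function(pairs, genes) {
  if (nrow(pairs) == 0L) {
    pairs$interchromosomal <- logical(0)
    return(pairs)
  }
  ma <- match(pairs$gene_a, genes$gene_id)
  mb <- match(pairs$gene_b, genes$gene_id)
  bad <- c(pairs$gene_a[is.na(ma)], pairs$gene_b[is.na(mb)])
  if (length(bad))
    stop("gene id(s) absent from gene table: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  keep <- genes$chromosome[ma] != genes$chromosome[mb]
  out <- pairs[keep, , drop = FALSE]
  out$interchromosomal <- TRUE
  out
}

# One EM run for a k-component Gaussian mixture on a numeric vector.
em_gauss <- function(x, k, mu0, sd0, w0, sd_floor = 0.05,
                     tol = 1e-8, maxit = 300L) {
  n <- length(x)
  mu <- mu0
  s <- pmax(sd0, sd_floor)
  w <- w0 / sum(w0)
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    lg <- vapply(seq_len(k),
                 function(j) log(w[j]) + dnorm(x, mu[j], s[j], log = TRUE),
                 numeric(n))
    lg <- matrix(lg, nrow = n)
    m <- apply(lg, 1L, max)
    lse <- m + log(rowSums(exp(lg - m)))
    ll <- sum(lse)
    r <- exp(lg - lse)
    nk <- colSums(r)
    if (any(nk < 1e-8)) break
    w <- nk / n
    mu <- colSums(r * x) / nk
    s <- pmax(sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk), sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(loglik = ll, mu = mu, sd = s, w = w, k = k)
}

em_fit_k <- function(x, k, restarts) {
  n <- length(x)
  best <- NULL
  qs <- quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  spread <- max(sd(x), 1e-3)
  for (r in seq_len(restarts)) {
    mu0 <- if (r == 1L) qs else qs + rnorm(k, 0, spread / 2)
    fit <- em_gauss(x, k, mu0, rep(spread, k), rep(1 / k, k))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

merge_small_components <- function(fit, weight_floor) {
  while (fit$k > 1L && any(fit$w < weight_floor)) {
    i <- which.min(fit$w)
    others <- setdiff(seq_len(fit$k), i)
    j <- others[which.min(abs(fit$mu[others] - fit$mu[i]))]
    w2 <- fit$w[i] + fit$w[j]
    mu2 <- (fit$w[i] * fit$mu[i] + fit$w[j] * fit$mu[j]) / w2
    m2 <- (fit$w[i] * (fit$sd[i]^2 + fit$mu[i]^2) +
           fit$w[j] * (fit$sd[j]^2 + fit$mu[j]^2)) / w2
    fit$mu[j] <- mu2
    fit$sd[j] <- sqrt(max(m2 - mu2^2, 1e-6))
    fit$w[j] <- w2
    fit$mu <- fit$mu[-i]
    fit$sd <- fit$sd[-i]
    fit$w <- fit$w[-i]
    fit$k <- fit$k - 1L
  }
  fit
}

#' Count Ks peaks by BIC-selected Gaussian mixtures on log-Ks
#'
#' Fits Gaussian mixtures with 1..`k_max` components to ln(Ks) by EM (seeded
#' restarts), selects the component count by minimal BIC, and merges
#' components lighter than `weight_floor` into their nearest neighbour.
#' Values outside `[ks_min, ks_max]` are discarded first: near-zero Ks
#' reflects alleles/very recent duplicates, and the Jukes-Cantor correction
#' is unreliable near saturation.
#'
#' @param ks Numeric vector of Ks values (NA/non-positive dropped).
#' @param k_max Maximum number of components to try (default 4).
#' @param weight_floor Minimum retained component weight (default 0.05).
#' @param ks_min,ks_max Analysis window on the Ks scale (defaults 0.05, 5).
#' @param restarts EM restarts per k (default 10).
#' @param seed Seed for the restart jitter.
#' @return Object of class `ks_mode_fit`: n_components, means, sds, weights
#'   (on the log-Ks scale, sorted by mean), bic_per_k, n_used.
#' @examples
#' set.seed(1)
#' fit <- fit_ks_modes(c(rlnorm(300, log(0.2), 0.15),
#'                       rlnorm(300, log(1.5), 0.15)))
#' fit$n_components
#' @export
fit_ks_modes <- function(ks, k_max = 4L, weight_floor = 0.05,
                         ks_min = 0.05, ks_max = 5, restarts = 10L,
                         seed = 1L) {
  x <- ks[is.finite(ks) & ks > 0 & ks >= ks_min & ks <= ks_max]
  if (length(x) < 50L)
    stop(sprintf(
      "insufficient data: need >= 50 usable Ks values, got %d", length(x)),
      call. = FALSE)
  lx <- log(x)
  n <- length(lx)
  fits <- with_rng(substream_seed(seed, "ksmodes"), {
    lapply(seq_len(k_max), function(k) em_fit_k(lx, k, restarts))
  })
  bic <- vapply(fits, function(f) -2 * f$loglik + (3 * f$k - 1) * log(n),
                numeric(1))
  names(bic) <- paste0("k", seq_len(k_max))
  fit <- merge_small_components(fits[[which.min(bic)]], weight_floor)
  o <- order(fit$mu)
  structure(list(n_components = fit$k,
                 means = fit$mu[o], sds = fit$sd[o], weights = fit$w[o],
                 bic_per_k = bic, n_used = n),
            class = "ks_mode_fit")
}

#' @export
print.ks_mode_fit <- function(x, ...) {
  cat(sprintf("<ks_mode_fit> %d component(s) over %d values\n",
              x$n_components, x$n_used))
  for (i in seq_len(x$n_components)) {
    cat(sprintf("  %d: Ks peak %.4g (log-mean %.4g, sd %.3g, weight %.3g)\n",
                i, exp(x$means[i]), x$means[i], x$sds[i], x$weights[i]))
  }
  cat("  BIC:", paste(sprintf("%s=%.1f", names(x$bic_per_k), x$bic_per_k),
                      collapse = " "), "\n")
  invisible(x)
}
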