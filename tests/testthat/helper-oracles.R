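# Independent oracles, implemented without reference to the package internals.

# Brute-force connected-component labelling by breadth-first search.
oracle_label_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  offs <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (mask[r0, c0] > 0 && lab[r0, c0] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r0, c0)); lab[r0, c0] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(offs))) {
          r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
          if (r >= 1 && r <= h && c >= 1 && c <= w &&
              mask[r, c] > 0 && lab[r, c] == 0L) {
            lab[r, c] <- cur
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

oracle_component_boxes <- function(lab) {
  ks <- sort(unique(lab[lab > 0]))
  t(vapply(ks, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    c(top = min(idx[, 1]) - 1L, left = min(idx[, 2]) - 1L,
      bottom = max(idx[, 1]), right = max(idx[, 2]),
      area = nrow(idx))
  }, numeric(5)))
}

# Mann-Whitney AUC: pairwise comparisons, ties counted 1/2.
oracle_auc_mw <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Exhaustive MCC-threshold sweep with an independent MCC formula.
oracle_best_threshold <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- unique(c(0, if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2, 1))
  best_th <- NA; best_mcc <- -Inf
  for (th in cand) {
    pred <- as.integer(scores >= th)
    tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    m <- if (den == 0) 0 else (tn * tp - fn * fp) / sqrt(den)
    if (m > best_mcc + 1e-12) { best_mcc <- m; best_th <- th }
  }
  list(threshold = best_th, mcc = best_mcc)
}

# High-resolution quadrature of the clean flow profile: the analytic
# sine-rise/exponential-decay shape is integrated on a fine grid, rescaled so
# its total equals fvc, and the cumulative volume is reported at `times`.
oracle_volume_trajectory <- function(fvc, pef, rise_time, decay_tau, duration,
                                     times, dt = 1e-4) {
  t <- seq(0, duration, by = dt)
  f <- ifelse(t <= rise_time, pef * sin(pi * t / (2 * rise_time)),
              pef * exp(-(t - rise_time) / decay_tau))
  v <- c(0, cumsum((head(f, -1) + tail(f, -1)) / 2 * dt))
  v <- v * fvc / v[length(v)]
  approx(t, v, xout = times)$y
}
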