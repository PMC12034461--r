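# Brute-force oracles kept deliberately independent of the package's
# implementation paths, plus small fixture builders.

assay <- SummarizedExperiment::assay
metadata <- S4Vectors::metadata

# naive rolling percentile: recompute stats::quantile on every clipped window
oracle_rolling_pct <- function(x, window, prob) {
  half <- window %/% 2
  vapply(seq_along(x), function(i) {
    w <- x[max(1, i - half):min(length(x), i + half)]
    quantile(w, prob, names = FALSE, type = 7)
  }, numeric(1))
}

# hand-rolled product-limit estimator: S(t) at each distinct event time
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  S <- 1
  out <- data.frame(time = numeric(), surv = numeric())
  for (t in ts) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    S <- S * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, surv = S))
  }
  out
}

# Efron partial log-likelihood for one binary covariate
oracle_efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sumD_x <- sum(x[D])
    rset <- sum(exp(beta * x[R]))
    dset <- sum(exp(beta * x[D]))
    ll <- ll + beta * sumD_x -
      sum(vapply(seq_len(d) - 1, function(l)
        log(rset - (l / d) * dset), numeric(1)))
  }
  ll
}

oracle_efron_mle <- function(time, event, x, interval = c(-8, 8)) {
  optimize(function(b) oracle_efron_loglik(b, time, event, x),
           interval = interval, maximum = TRUE, tol = 1e-10)$maximum
}

# build an ActivityRaster straight from a 0/1 matrix
make_raster <- function(m, frameRate = 1.1) {
  mode(m) <- "integer"
  if (nrow(m) > 0 && is.null(rownames(m)))
    rownames(m) <- paste0("n", seq_len(nrow(m)))
  new("ActivityRaster", SummarizedExperiment::SummarizedExperiment(
    assays = list(active = m),
    metadata = list(frame_rate = frameRate,
                    params = list(k = NA, minFrames = 1L))))
}

# raster implied by the ground-truth log (participants active over the full
# event window), bypassing the transient detector
truth_raster <- function(truth, ids, nFrames, frameRate = 1.1) {
  m <- matrix(0L, length(ids), nFrames, dimnames = list(ids, NULL))
  iv <- trueEventIntervals(truth)
  tp <- trueParticipants(truth)
  for (e in seq_len(nrow(iv))) {
    cols <- (iv[e, 1] + 1):iv[e, 2]
    m[tp[[e]], cols] <- 1L
  }
  make_raster(m, frameRate)
}

# small deterministic survival table generator for oracle comparisons
random_survival_table <- function(n, seed) {
  withr::with_seed(seed, data.frame(
    neuron_id = paste0("n", seq_len(n)),
    cluster_id = sample(paste0("c", 1:3), n, replace = TRUE),
    group = factor(sample(c("a", "b"), n, replace = TRUE),
                   levels = c("a", "b")),
    time = sample(1:10, n, replace = TRUE),
    event = rbinom(n, 1, 0.6)))
}
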