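# Independent oracles used by the property tests. Kept deliberately separate
# in style and route from the package implementation.

# Decision-table oracle for the censoring-aware response label. Branches on
# (treated censored?, how many controls censored?) and computes the gain as a
# plain weighted mean over the contributing controls.
oracle_label <- function(t_os, t_c, c_os, c_c, w, thr) {
  k <- length(c_os)
  wmean <- function(idx) sum(c_os[idx] * w[idx]) / sum(w[idx])
  if (sum(c_c) == k) {           # every control censored
    if (t_c == 1) return("undetermined")
    if (t_os - wmean(seq_len(k)) >= thr) "undetermined" else "non_response"
  } else {                       # at least one observed control contributes
    sg <- t_os - wmean(which(c_c == 0))
    if (t_c == 1) {
      if (sg >= thr) "response" else "undetermined"
    } else {
      if (sg >= thr) "response" else "non_response"
    }
  }
}

# Brute-force k-NN: rank every control by |PS difference| (ties by id) and
# take the first k.
oracle_nn <- function(ps_t, ps_c, k, cids = seq_along(ps_c)) {
  tab <- data.frame(d = abs(ps_c - ps_t), id = cids)
  tab <- tab[order(tab$d, tab$id), ]
  tab$id[seq_len(k)]
}

# Minimal hand-built cohort for estimator tests: ids 1..n, explicit values.
toy_cohort <- function(z, os, cens, X = NULL) {
  n <- length(z)
  d <- data.frame(id = seq_len(n), z = z, os_months = os, censored = cens)
  if (is.null(X)) {
    X <- matrix(stats::rnorm(n * 10), n, 10)
  }
  colnames(X) <- paste0("x", 1:10)
  cbind(d, as.data.frame(X))
}
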