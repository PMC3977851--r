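# Independent oracles used across the suite. These deliberately use naive
# formulations (pairwise counting, exhaustive enumeration) so they share no
# code path with the package implementations they check.

# U statistic by direct pairwise comparison (ties count 1/2)
oracle_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# exact Mann-Whitney p by enumerating every group assignment
oracle_mw_p <- function(a, b, tail) {
  pooled <- c(a, b)
  na <- length(a)
  u_obs <- oracle_u(a, b)
  sets <- combn(length(pooled), na)
  us <- apply(sets, 2, function(ix) oracle_u(pooled[ix], pooled[-ix]))
  mu <- na * length(b) / 2
  if (tail == "two_sided") mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  else mean(us >= u_obs - 1e-9)
}

# exact Wilcoxon signed-rank p by enumerating every sign pattern
oracle_wilcoxon_p <- function(pre, post, tail) {
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  if (tail == "two_sided") mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
  else mean(vs >= v_obs - 1e-9)
}

# exhaustive MAP search over all 2^n labelings of a small grid
oracle_map_energy <- function(intensity, params) {
  n <- length(intensity)
  best <- Inf
  for (code in 0:(2^n - 1)) {
    lab <- as.integer(intToBits(code))[seq_len(n)]
    e <- mrf_energy(intensity, array(lab, dim = dim(intensity)), params)
    if (e < best) best <- e
  }
  best
}

# hand simulation of the GrowCut conquest rule on a 1-D cell row
oracle_growcut_1d <- function(feature, labels, strengths, max_iters = 100) {
  n <- length(feature)
  maxc <- max(abs(feature))
  if (maxc <= 0) maxc <- 1
  for (it in seq_len(max_iters)) {
    lab2 <- labels
    th2 <- strengths
    for (p in seq_len(n)) {
      for (q in c(p - 1, p + 1)) {
        if (q < 1 || q > n || labels[q] == 0) next
        g <- 1 - abs(feature[p] - feature[q]) / maxc
        if (g * strengths[q] > th2[p]) {
          th2[p] <- g * strengths[q]
          lab2[p] <- labels[q]
        }
      }
    }
    if (identical(lab2, labels) && identical(th2, strengths)) break
    labels <- lab2
    strengths <- th2
  }
  list(labels = labels, strengths = strengths)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
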