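# Small in-code fixtures and independent reference implementations used
# across the suite.

expr_text <- function(...) paste(c(...), collapse = "\n")

tiny_expression <- function() {
  expr_text(
    "ID\tSYM\tA1\tA2\tA3\tA4",
    "g1\tGENE1\t1.0\t2.0\t3.0\t4.0",
    "g2\tGENE2\t2.0\t\t1.5\t0.5",
    "g3\tGENE3\t-1\t0\t1\t2")
}

tiny_labels <- function(paired = FALSE) {
  lines <- c(
    "Array\tA1\tA2\tA3\tA4",
    "Treatment\talpha\talpha\tcontrol\tcontrol",
    "Replicate\t1\t1\t1\t1",
    "Time\t0\t4\t0\t4")
  if (paired) lines <- c(lines, "Paired\tyes\t\t\t")
  expr_text(lines)
}

tiny_dataset <- function(paired = FALSE) {
  assemble_dataset(
    read_expression_matrix(textConnection(tiny_expression())),
    read_design_table(textConnection(tiny_labels(paired))))
}

sim_dataset <- function(...) simulated_st_dataset(simulate_dataset(...))

# independent oracle: dense trapezoid integration of the piecewise-linear
# interpolant on a 1e-4 grid (augmented with the measurement knots so the
# dense sum is not biased at the kinks)
riemann_auc <- function(times, values, t_start, t_end, step = 1e-4) {
  xs <- sort(unique(c(seq(t_start, t_end, by = step), t_end,
                      times[times > t_start & times < t_end])))
  ys <- approx(times, values, xout = xs)$y
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

# independent naive silhouette (double loop, no shared code)
naive_silhouette <- function(x, cl, metric = "euclidean") {
  n <- nrow(x)
  d <- function(i, j) if (metric == "euclidean")
    sqrt(sum((x[i, ] - x[j, ])^2)) else sum(abs(x[i, ] - x[j, ]))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), 0))
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(kk) {
      mean(vapply(which(cl == kk), function(j) d(i, j), 0))
    }, 0))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# brute-force Mann-Whitney two-sided p by enumerating group assignments
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  mu <- na * length(b) / 2
  idx <- combn(n, na)
  us <- apply(idx, 2, function(ii) u_stat(pooled[ii], pooled[-ii]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# brute-force permutation p on the Welch t statistic
enumerate_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  tstat <- function(x, y) {
    md <- mean(x) - mean(y)
    se <- sqrt(var(x) / length(x) + var(y) / length(y))
    if (se == 0) { if (md == 0) 0 else sign(md) * Inf } else md / se
  }
  t_obs <- tstat(a, b)
  idx <- combn(n, na)
  ts <- apply(idx, 2, function(ii) tstat(pooled[ii], pooled[-ii]))
  mean(abs(ts) >= abs(t_obs) * (1 - 1e-12))
}
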