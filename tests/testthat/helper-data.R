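# Shared fixtures, built in code.

# A cheap trainer configuration for unit tests that only exercise plumbing
# (full defaults are used wherever a test asserts fit quality).
quick_cfg <- function(seed = 1) {
  train_config(max_epochs = 300, patience = 50, n_restarts = 1, seed = seed)
}

# Tiny two-substrate summary in the fixture schema, for generator tests.
tiny_summary <- function() {
  data.frame(
    label = c("A(70)+B(30)", "B(80)+D(20)"),
    bs_pct = c(70, 0), hs_pct = c(0, 80), wb_pct = c(30, 0),
    rb_pct = c(0, 20), cn_ratio = c(49, 112), n = c(12, 12),
    srp_mean = c(20, 40), srp_se = c(0.3, 0.6),
    dphf_mean = c(28, 46), dphf_se = c(1.0, 0.9),
    dffh_mean = c(31, 51), dffh_se = c(0.7, 0.7),
    nfb_mean = c(9, 6), nfb_se = c(0.6, 0.6),
    yield_mean = c(130, 70), yield_se = c(0.9, 0.3),
    be_mean = c(52.5, 28.3), be_se = c(0.4, 0.2),
    tcp_mean = c(44, 60), tcp_se = c(0.9, 0.9)
  )
}

# A smooth, noiseless, nonlinear response of the four inputs —
# representable by a small tansig network.
smooth_benchmark <- function(n = 150, seed = 5) {
  set.seed(seed)
  X <- matrix(runif(n * 4, 0, 100), n, 4)
  colnames(X) <- substrate_components()
  y <- 50 * tanh((X[, 1] - X[, 2]) / 40) + 0.3 * X[, 3]
  data.frame(X, resp = y)
}
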