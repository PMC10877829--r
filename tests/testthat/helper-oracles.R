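# Independent brute-force oracles and fixture generators.

# tie-free random score set
random_score_set <- function(n_x, n_y, shift = 1) {
  score_set(rnorm(n_x, mean = shift), rnorm(n_y))
}

# literal double-sum Mann-Whitney AUC (Bamber form, strict inequality)
auc_mw_loop <- function(x, y) {
  mean(outer(x, y, ">"))
}

# literal double-sum two-way trimmed U-statistic with clamped-floor survival
# inverses, written independently of the package internals
tpauc_trimmed_loop <- function(x, y, b_se, b_sp) {
  inv_surv <- function(s, u) {
    s <- sort(s)
    n <- length(s)
    s[min(max(floor((1 - u) * n + 1e-9), 1), n)]
  }
  x_cut <- inv_surv(x, b_se)
  y_cut <- inv_surv(y, 1 - b_sp)
  total <- 0
  for (xi in x) {
    for (yj in y) {
      total <- total + (xi > yj && xi <= x_cut && yj >= y_cut)
    }
  }
  total / (length(x) * length(y))
}

# correlated paired-classifier fixture (shared latent signal)
make_paired_data <- function(n_x = 60, n_y = 80, seed = 41) {
  set.seed(seed)
  labels <- c(rep(1, n_x), rep(0, n_y))
  signal <- rnorm(n_x + n_y)
  list(labels = labels,
       p1 = signal + 1.2 * labels + rnorm(n_x + n_y, sd = 0.5),
       p2 = signal + 0.7 * labels + rnorm(n_x + n_y, sd = 0.5))
}

# hand fixture used throughout the spec-level checks
hand_set <- function() score_set(c(3, 1), c(2, 0))
hand_roc <- function() build_empirical_roc(hand_set())
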