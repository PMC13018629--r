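# shared fixtures built in code

# the peaked division schedule used across recovery studies
peaked_schedule <- function() division_schedule(2, 6, 3, 2, 8)

# logistic growth rate with mu_max = 2 /h, stationary entry at 4 h
logistic_mu <- function() function(t) logistic_rate(t, t_s = 4, mu_max = 2)

# sup-norm relative error between two k(t) curves on a time grid
k_supnorm <- function(sched_hat, sched_true, tt) {
  max(abs(k_of_t(sched_hat, tt) - k_of_t(sched_true, tt)) /
        k_of_t(sched_true, tt))
}

# random per-cell table with valid capsule geometry
random_cells <- function(n, seed = 1, condition = "a", time_h = 0) {
  set.seed(seed)
  w <- runif(n, 0.3, 1.4)
  l <- w * runif(n, 1.01, 8)
  data.frame(cell_id = sprintf("c%04d", seq_len(n)),
             condition = condition, time_h = time_h,
             projected_area_um2 = capsule_area(l, w), length_um = l)
}
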