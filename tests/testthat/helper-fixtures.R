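# Small in-code fixtures shared across test files.

tiny_cohort <- function(n_cancer = 8L, n_control = 10L, n_sensors = 3L,
                        T = 40L, seed = 1L, ...) {
  simulate_cohort(sim_config(n_cancer = n_cancer, n_control = n_control,
                             n_sensors = n_sensors, T = T, seed = seed, ...))
}

tiny_panels <- function(...) {
  co <- tiny_cohort(...)
  co <- suppressMessages(screen_cohort(co))
  prep <- suppressMessages(preprocess_cohort(co))
  list(panels = prep$panels, labels = cohort_labels(co),
       prep = prep, cohort = co)
}

# panel with two well-separated shape groups and known group labels
two_group_panel <- function(n_per = 10L, T = 30L, noise = 0.02, seed = 1L) {
  set.seed(seed)
  t <- seq_len(T)
  up <- 1 + t / T
  down <- 2 - t / T
  curves <- rbind(
    t(replicate(n_per, up + rnorm(T, 0, noise))),
    t(replicate(n_per, down + rnorm(T, 0, noise))))
  rownames(curves) <- sprintf("m%02d", seq_len(2L * n_per))
  list(curves = curves, groups = rep(1:2, each = n_per))
}
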