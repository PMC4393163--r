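# Builders for standardized tables and balanced crossed designs used by the
# universality and acceptance tests.

std_tab <- function(z, subjects, day = NULL, time_slot = NULL) {
  n <- nrow(z)
  structure(list(
    labels = data.frame(subject_id = subjects,
                        day = if (is.null(day)) rep(1L, n) else day,
                        time_slot = if (is.null(time_slot)) rep(1L, n)
                                    else time_slot,
                        trial = seq_len(n)),
    z = as.data.frame(z)),
    class = "standardized_table")
}

sim_crossed <- function(s2_sub, s2_e, seed, ns = 15, nd = 3, nt = 5, nr = 4,
                        s2_day = 0, s2_time = 0) {
  set.seed(seed)
  sub <- rep(sprintf("S%02d", 1:ns), each = nd * nt * nr)
  day <- rep(rep(1:nd, each = nt * nr), ns)
  tim <- rep(rep(1:nt, each = nr), ns * nd)
  y <- rep(rnorm(ns, 0, sqrt(s2_sub)), each = nd * nt * nr) +
    rnorm(nd, 0, sqrt(s2_day))[day] +
    rnorm(nt, 0, sqrt(s2_time))[tim] +
    rnorm(length(sub), 0, sqrt(s2_e))
  std_tab(data.frame(I1 = y), sub, day, tim)
}
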