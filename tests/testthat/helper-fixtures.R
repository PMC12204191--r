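# Heavyweight fixtures computed once per test run and shared across files.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# The default study cohort (14 HC + 30 TLE) analysed end to end.
default_analysis <- function() fixture("default_analysis", {
  analyze_cohort(generate_cohort(sim_config()))
})

# A small cohort for cheaper structural tests.
small_cohort <- function() fixture("small_cohort", {
  generate_cohort(sim_config(n_hc = 2, n_tle = 3, seed = 42))
})

small_analysis <- function() fixture("small_analysis", {
  analyze_cohort(small_cohort())
})

# A null configuration: both groups share the HC behavioural block and both
# conditions share the correct-trial block, so no group or condition effect
# remains downstream.
null_config <- function(n_hc = 10, n_tle = 10, seed = 77, subject_sd = 0) {
  base <- sim_config()
  sim_config(
    n_hc = n_hc, n_tle = n_tle, seed = seed, subject_sd = subject_sd,
    groups = list(TLE = base$groups$HC),
    conditions = list(incorrect = base$conditions$correct)
  )
}

# Hand-built trial record: piecewise-constant gaze with given AOI schedule.
# `schedule` is a data.frame(aoi, duration); positions sit at box centres.
make_test_trial <- function(schedule, layout = default_retrieval_layout(),
                            rate = 100, condition = "correct",
                            group = "HC", pupil = 3.5) {
  centres <- lapply(layout$boxes, function(b) c((b[1] + b[3]) / 2,
                                                (b[2] + b[4]) / 2))
  total <- sum(schedule$duration)
  m <- round(total * rate)
  t <- (seq_len(m) - 1) / rate
  bounds <- c(0, cumsum(schedule$duration))
  seg <- pmin(findInterval(t, bounds, rightmost.closed = TRUE),
              nrow(schedule))
  xy <- t(vapply(seg, function(s) {
    a <- schedule$aoi[s]
    if (a == "off") c(5, 5) else centres[[a]]
  }, c(0, 0)))
  samples <- data.frame(t = t, x = xy[, 1], y = xy[, 2],
                        pupil = rep_len(pupil, m), valid = TRUE)
  structure(list(subject_id = "T01", trial_id = 1L, phase = "retrieval",
                 trial_type = "direct", block = 1L, condition = condition,
                 group = group, aoi = layout, samples = samples,
                 response_time = total, excluded = FALSE),
            class = "gaze_trial")
}
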