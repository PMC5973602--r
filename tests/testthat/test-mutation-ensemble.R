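test_that("transition table encodes the phenotype-step classes", {
  mp <- mutation_params()
  tt <- transition_table(mp)
  expect_equal(nrow(tt), 6)
  one <- tt[tt$class == "one_step", ]
  expect_setequal(paste(one$source, one$target, sep = ">"),
                  c("00>01", "00>10", "10>11", "10>00"))
  expect_true(all(one$prob == mp$p_major))
  two <- tt[tt$class == "two_step", ]
  expect_setequal(paste(two$source, two$target, sep = ">"),
                  c("00>11", "01>10"))
  expect_true(all(two$prob == mp$p_double))
  # conditional probability mass per source stays below 1
  expect_true(all(tapply(tt$prob, tt$source, sum) <= 1))
  expect_error(mutation_params(rate = 2), "rate")
  expect_error(mutation_params(p_major = 0.5), "exceed 1")
})

test_that("mutation kernel draws Poisson counts at the printed rates", {
  mp <- mutation_params()
  # empty tumor: no events, ever
  expect_equal(nrow(mutation_kernel(tumor_state(rep(0, 4), 0), 1, mp)), 0)
  # fixed seed: identical event stream on replay
  s <- tumor_state(c(1e10, 0, 1e10, 0), R = 0)
  set.seed(9)
  a <- mutation_kernel(s, 1, mp)
  set.seed(9)
  b <- mutation_kernel(s, 1, mp)
  expect_identical(a, b)
  # empirical mean of the 00 -> 01 count matches n * rate * p_major
  set.seed(10)
  draws <- replicate(400, {
    ev <- mutation_kernel(s, 1, mp)
    sum(ev$count[ev$source == "00" & ev$target == "01"])
  })
  expect_equal(mean(draws), 1e10 * 2e-7 * (1 / 500), tolerance = 0.1)
  expect_error(mutation_kernel(s, dt = 0, mp), "dt")
})

test_that("lineage scoring follows the threshold rules", {
  # monotone growth past the threshold
  up <- invasion_success(pop = c(1, 5, 40, 150, 400),
                         N = rep(1e5, 5))
  expect_identical(up$status, "established")
  expect_identical(up$index, 4L)
  # extinction
  down <- invasion_success(pop = c(1, 0.4, 0), N = rep(1e5, 3))
  expect_identical(down$status, "failed")
  # borderline lineage at the horizon resolves by growth advantage
  pend <- invasion_success(pop = c(1, 2, 4), N = rep(1e5, 3))
  expect_identical(pend$status, "pending")
  expect_identical(
    invasion_success(c(1, 2, 4), rep(1e5, 3), final_percap = 0.01)$status,
    "established")
  expect_identical(
    invasion_success(c(1, 2, 4), rep(1e5, 3), final_percap = -0.01)$status,
    "failed")
  # the 0.1%-of-N leg of the threshold binds in large tumors
  big <- invasion_success(pop = c(1, 150, 120), N = rep(1e6, 3))
  expect_identical(big$status, "pending")
})

test_that("zero mutation rate reduces to the deterministic run", {
  p <- model_params()
  sim <- simulate_tumor(p, mutation_params(rate = 0), horizon = 600,
                        seed = 4)
  expect_equal(nrow(sim$record$events), 0)
  expect_identical(sim$record$fate, "cheater_only")
  expect_equal(sum(sim$record$final_state$n), p$k, tolerance = 1e-3)
  det <- integrate_tumor(p, tumor_state(c(1000, 0, 0, 0), R = 1),
                         horizon = 600)
  # chunked restarts change the solver's step sequence, not the solution
  expect_equal(sim$trajectory$states, det$states, tolerance = 1e-5)
})

test_that("hybrid simulation is reproducible from its seed", {
  p <- model_params()
  mp <- mutation_params(rate = 2e-4)  # frequent events exercise the path
  a <- simulate_tumor(p, mp, horizon = 300, seed = 12)
  b <- simulate_tumor(p, mp, horizon = 300, seed = 12)
  expect_identical(a$record$events, b$record$events)
  expect_identical(a$trajectory$states, b$trajectory$states)
  c <- simulate_tumor(p, mp, horizon = 300, seed = 13)
  expect_false(identical(a$record$events, c$record$events))
})

test_that("mutant arrivals seed one-cell lineages that are then scored", {
  p <- model_params()
  mp <- mutation_params(rate = 5e-5)
  sim <- simulate_tumor(p, mp, horizon = 1500, seed = 2)
  ev <- sim$record$events
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$source %in% c("00", "01", "10", "11")))
  expect_true(all(paste(ev$source, ev$target) %in%
                    paste(transition_table(mp)$source,
                          transition_table(mp)$target)))
  expect_true(all(ev$outcome %in% c("established", "failed")))
  # arrivals into the founding tumor are labelled cheater-only
  expect_true(all(ev$resident[ev$t < 200] == "cheater_only"))
})

test_that("fate classification follows composition and establishment", {
  p <- model_params()
  # local producers take over: cheaters die out, no metastatic lineage
  # strong specificity: cheaters are excluded outright despite the
  # slow-manifold lag of the growing resource
  p2 <- model_params(beta1 = 2)
  sim <- simulate_tumor(p2, mutation_params(rate = 0), horizon = 3650,
                        seed = 3,
                        initial = tumor_state(c(1e3, 0, 2e6, 0),
                                              R = 1e6))
  expect_identical(sim$record$fate, "producer_only")
  expect_false(is.na(sim$record$fate_time))
  expect_equal(sim$record$final_state$n[["00"]], 0)
  expect_gt(sum(sim$record$final_state$n), p2$k)
  # an established secondary-producer lineage dominates the label
  mp <- mutation_params(rate = 5e-5)
  sim2 <- simulate_tumor(p, mp, horizon = 2500, seed = 5)
  est <- sim2$record$events$outcome == "established" &
    sim2$record$events$target %in% c("01", "11")
  expect_true(any(est))
  expect_identical(sim2$record$fate, "metastasis_competent")
  expect_equal(sim2$record$fate_time,
               min(sim2$record$events$outcome_t[est]))
})

test_that("ensembles aggregate records and reproduce bit for bit", {
  p <- model_params()
  mp <- mutation_params(rate = 1e-4)
  e1 <- run_ensemble(4, p, mp, horizon = 400, master_seed = 99)
  e2 <- run_ensemble(4, p, mp, horizon = 400, master_seed = 99)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_identical(e1$summary$fates, e2$summary$fates)
  df <- as.data.frame(e1)
  expect_equal(nrow(df), 4)
  expect_true(all(df$fate %in% c("cheater_only", "producer_only",
                                 "coexistence", "metastasis_competent")))
  # single-tumor ensemble reduces to simulate_tumor under the same seed
  e3 <- run_ensemble(1, p, mp, horizon = 400, master_seed = 7)
  set.seed(7)
  seed1 <- sample.int(.Machine$integer.max - 1L, 1)
  solo <- simulate_tumor(p, mp, horizon = 400, seed = seed1)
  expect_identical(e3$records[[1]]$events, solo$record$events)
  out <- withr::local_tempdir()
  write_ensemble(e1, out)
  expect_true(file.exists(file.path(out, "tumors.csv")))
  recs <- jsonlite::read_json(file.path(out, "records.json"))
  expect_length(recs, 4)
  expect_error(run_ensemble(0, p, mp), "at least 1")
})
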