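test_that("hand-computed KL average matches model_uncertainty arithmetic", {
  ## two members (0.8, 0.2) and (0.2, 0.8) with the ensemble-mean reference
  p1 <- c(0.8, 0.2); p2 <- c(0.2, 0.8); ref <- (p1 + p2) / 2
  kl <- function(a, b) sum(a * (log(a) - log(b)))
  u_hand <- (kl(p1, ref) + kl(p2, ref)) / 2
  expect_equal(u_hand, 0.19274, tolerance = 1e-4)
})

test_that("uncertainty is zero for identical members and non-negative always", {
  ds <- small_dataset()
  ag <- small_agent()
  ens <- structure(list(members = list(ag, ag, ag), fraction = 0.3, seed = 1),
                   class = "c51_ensemble")
  S <- ds$states[1:7, ]
  u <- model_uncertainty(ens, S)
  expect_equal(max(abs(u)), 0, tolerance = 1e-12)
  ens2 <- small_ensemble()
  u2 <- model_uncertainty(ens2, S)
  expect_true(all(u2 >= 0))
  expect_gt(max(u2), 0)
})

test_that("the estimator is invariant to member ordering and honors the reference", {
  ens <- small_ensemble()
  S <- small_dataset()$states[3:9, ]
  u_a <- model_uncertainty(ens, S)
  ens_rev <- ens; ens_rev$members <- rev(ens$members)
  expect_equal(model_uncertainty(ens_rev, S), u_a, tolerance = 1e-12)
  ## full-model reference requires the model and differs in general
  expect_error(model_uncertainty(ens, S, reference = "full_model"),
               "full_model")
  u_f <- model_uncertainty(ens, S, reference = "full_model",
                           full_model = small_agent())
  expect_true(all(u_f >= 0))
})

test_that("patient-weighted mixture follows the stated arithmetic", {
  ens <- small_ensemble()
  S <- small_dataset()$states[1:4, ]
  d <- lapply(ens$members, c51_distributions, states = S)
  ## one member takes all the weight
  eq1 <- ensemble_q(ens, S, weights = c(1, 0, 0))
  expect_equal(eq1$dist, d[[1]], tolerance = 1e-12)
  ## 600/300 mixing on two members
  eq2 <- ensemble_q(structure(list(members = ens$members[1:2]),
                              class = "c51_ensemble"),
                    S, weights = c(600, 300))
  expect_equal(eq2$dist, (600 * d[[1]] + 300 * d[[2]]) / 900, tolerance = 1e-12)
  ## default weights are the member n_patients
  eqd <- ensemble_q(ens, S)
  w <- vapply(ens$members, function(m) m$n_patients, numeric(1))
  mix <- Reduce(`+`, Map(function(di, wi) wi * di, d, w / sum(w)))
  expect_equal(eqd$dist, mix, tolerance = 1e-12)
})

test_that("bootstrap members differ in data but share architecture", {
  ens <- small_ensemble()
  expect_equal(length(ens$members), 3L)
  expect_error(fit_c51_ensemble(small_dataset(), n_members = 1), "at least 2")
  np <- vapply(ens$members, function(m) m$n_patients, numeric(1))
  tr_pid <- unique(small_dataset()$patient_id[small_dataset()$split == "train"])
  ## sampling with replacement at fraction 0.4: distinct patients < drawn
  expect_true(all(np <= round(0.4 * length(tr_pid))))
  expect_true(all(np > 0.2 * length(tr_pid)))
  ## members disagree somewhere
  S <- small_dataset()$states[1:20, ]
  q1 <- predict(ens$members[[1]], S)$Q
  q2 <- predict(ens$members[[2]], S)$Q
  expect_gt(max(abs(q1 - q2)), 0)
})

test_that("voting policy counts member votes against the threshold", {
  ens <- small_ensemble()
  S <- small_dataset()$states[1:30, ]
  votes <- vapply(ens$members, function(m)
    action_has_vaso(predict(m, S)$greedy - 1L), logical(nrow(S)))
  agree <- 100 * rowMeans(votes)
  ## strict threshold: a single dissenter blocks at p = 100
  v100 <- voting_vaso_policy(ens, S, p = 100)
  expect_equal(v100$vaso, agree >= 100)
  ## permissive threshold: any member voting vaso suffices
  v1 <- voting_vaso_policy(ens, S, p = 1e-6)
  expect_equal(v1$vaso, agree > 0)
  ## p = 50 with 2 of 3 agreeing prescribes vasopressors
  expect_equal(voting_vaso_policy(ens, S, p = 50)$vaso, agree >= 50)
  ## chosen action is consistent with the vaso flag
  v50 <- voting_vaso_policy(ens, S, p = 50)
  expect_equal(action_has_vaso(v50$action), v50$vaso)
})

test_that("out-of-distribution states carry higher mean uncertainty", {
  ens <- small_ensemble()
  ds <- small_dataset()
  set.seed(31)
  idx <- sample(which(ds$split == "validation"), 60)
  S_in <- ds$states[idx, ]
  S_out <- S_in
  vital_cols <- match(c("hr", "sbp", "dbp", "map"), ds$feature_names)
  S_out[, vital_cols] <- S_out[, vital_cols] + 5   # +5 SD shift
  u_in <- mean(model_uncertainty(ens, S_in))
  u_out <- mean(model_uncertainty(ens, S_out))
  expect_gt(u_out, u_in)
})
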