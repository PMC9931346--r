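normal_inputs <- list(pao2_fio2 = 500, platelets = 250, bilirubin = 0.5,
                      map = 80, vasopressor = 0, gcs = 15, creatinine = 0.9)

test_that("respiratory PaO2/FiO2 bands map to the printed components", {
  s <- do.call(sofa_score, modifyList(normal_inputs,
                                      list(pao2_fio2 = c(500, 350, 250, 150, 90))))
  expect_equal(s$respiration, c(0, 1, 2, 3, 4))
  expect_equal(s$total, c(0, 1, 2, 3, 4))
  expect_error(sofa_score(pao2 = 90, fio2 = 0, platelets = 250,
                          bilirubin = 0.5, map = 80, gcs = 15,
                          creatinine = 0.9), "FiO2")
})

test_that("SOFA total sums components and is monotone in worsening inputs", {
  s0 <- do.call(sofa_score, normal_inputs)
  expect_equal(s0$total, 0)
  expect_equal(s0$total, sum(s0[1, 1:6]))
  # worsening any single input never lowers the total
  worsen <- list(pao2_fio2 = c(500, 350, 250, 150, 90),
                 platelets = c(250, 140, 90, 40, 10),
                 bilirubin = c(0.5, 1.5, 3, 7, 13),
                 gcs = c(15, 14, 11, 7, 4),
                 creatinine = c(0.9, 1.5, 2.5, 4, 6),
                 vasopressor = c(0, 0, 0.05, 0.05, 0.3))
  for (input in names(worsen)) {
    tots <- do.call(sofa_score,
                    modifyList(normal_inputs,
                               worsen[input]))$total
    expect_true(all(diff(tots) >= 0), info = input)
  }
  # every component stays in 0..4
  s <- do.call(sofa_score, lapply(worsen, function(v) v[5]))
  expect_true(all(as.matrix(s[1, 1:6]) %in% 0:4))
  expect_equal(s$total, sum(s[1, 1:6]))
})

test_that("SIRS counts met criteria and flags at the threshold", {
  mid <- sirs_score(hr = 75, temp = 37, rr = 16, paco2 = 40, wbc = 8)
  expect_equal(mid$score, 0); expect_false(mid$flag)
  all4 <- sirs_score(hr = 100, temp = 39, rr = 25, paco2 = 40, wbc = 15)
  expect_equal(all4$score, 4); expect_true(all4$flag)
  # every 2-of-4 combination flags at threshold 2 (enumeration oracle)
  abn <- list(hr = c(75, 100), temp = c(37, 39), resp = c(16, 25),
              wbc = c(8, 2))
  for (pair in combn(4, 2, simplify = FALSE)) {
    on <- seq_len(4) %in% pair
    r <- sirs_score(hr = abn$hr[1 + on[1]], temp = abn$temp[1 + on[2]],
                    rr = abn$resp[1 + on[3]], paco2 = 40,
                    wbc = abn$wbc[1 + on[4]])
    expect_equal(r$score, 2)
    expect_true(r$flag)
  }
  # PaCO2 below 32 meets the respiratory criterion on its own
  expect_equal(sirs_score(75, 37, 16, 30, 8)$score, 1)
  # configurable threshold
  expect_false(sirs_score(100, 39, 16, 40, 8, threshold = 3)$flag)
})

test_that("pass-through mortality counts each patient once per state", {
  # the worked trajectory: A1 -> A2 -> A1, patient dies
  r <- state_mortality(list(c(1, 2, 1)), patient_id = "p1",
                       died = c(p1 = TRUE), K = 3)
  expect_equal(r$n_patients[1:2], c(1L, 1L))
  expect_equal(r$n_died[1:2], c(1L, 1L))
  expect_equal(r$mortality[1:2], c(1, 1))
  expect_true(is.na(r$mortality[3]))
  # all survive
  r0 <- state_mortality(list(c(1, 2), c(2, 1)), c("a", "b"),
                        c(a = FALSE, b = FALSE), K = 2)
  expect_equal(r0$mortality, c(0, 0))
  # random cohort against a brute-force counting oracle
  set.seed(31)
  K <- 4
  seqs <- replicate(60, sample.int(K, sample(2:10, 1), replace = TRUE),
                    simplify = FALSE)
  pat <- sample(paste0("p", 1:25), 60, replace = TRUE)
  died <- setNames(sample(c(TRUE, FALSE), 25, replace = TRUE),
                   paste0("p", 1:25))
  r <- state_mortality(seqs, pat, died, K)
  for (k in seq_len(K)) {
    pk <- unique(pat[vapply(seqs, function(s) k %in% s, TRUE)])
    expect_equal(r$n_patients[k], length(pk))
    expect_equal(r$mortality[k], mean(died[pk]))
  }
  # duplicating consecutive labels changes nothing
  seqs2 <- lapply(seqs, function(s) rep(s, each = 2))
  expect_equal(state_mortality(seqs2, pat, died, K), r)
  # denominators sum to at least the number of distinct visiting patients
  expect_gte(sum(r$n_patients), length(unique(pat)))
})

test_that("state summaries match a brute-force group-by", {
  set.seed(5)
  X <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, paste0("v", 1:5)))
  labels <- sample.int(3, 60, replace = TRUE)
  s <- summarize_states(X, labels)
  for (k in 1:3) {
    for (j in 1:5) {
      expect_equal(s$mean[k, j], mean(X[labels == k, j]), tolerance = 1e-12)
      expect_equal(s$sd[k, j], sd(X[labels == k, j]), tolerance = 1e-12)
    }
  }
  one <- summarize_states(matrix(7, 4, 1), rep(1, 4))
  expect_equal(unname(one$mean[1, 1]), 7)
  expect_equal(unname(one$sd[1, 1]), 0)
  expect_warning(summarize_states(X, rep(1, 60), K = 2), "empty")
})
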