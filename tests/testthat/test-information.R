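test_that("SNR closed forms: [2,4] gives 4.5; degenerate and scaled inputs behave", {
  r <- snr(c(2, 4))
  expect_equal(r$S, 3)
  expect_equal(r$sigma2, 2)
  expect_equal(r$snr, 4.5)

  flat <- snr(rep(7, 5))
  expect_true(is.infinite(flat$snr))
  expect_true(flat$degenerate)

  set.seed(2)
  v <- rpois(20, 4) + 1
  expect_equal(snr(v)$snr, snr(3 * v)$snr, tolerance = 1e-12)
})

test_that("SNR is computed per contrast from cyclewise counts", {
  p <- make_stimulus(c(30, 50), repeats = 3, randomize = FALSE)
  s <- quantal_series(c(0.05, 0.25, 0.45, 0.65, 0.85, 1.05),
                      c(1L, 2L, 1L, 3L, 2L, 4L))
  out <- snr(count_per_cycle(s, p))
  expect_equal(nrow(out), 2)
  expect_equal(out$contrast, c(30, 50))
  expect_equal(out$S[1], mean(c(1, 2, 1)))
  expect_equal(out$snr[1], mean(c(1, 2, 1))^2 / var(c(1, 2, 1)))
})

test_that("binning tiles cycles exactly and flags multi-event bins", {
  p <- make_stimulus(60, repeats = 1, randomize = FALSE)   # one 200-ms cycle
  s <- quantal_series(0.03, 2L)
  b <- bin_events(s, p, bin_width = 0.02)
  expect_equal(attr(b, "bins_per_cycle"), 10L)
  expect_equal(nrow(b), 10L)
  expect_equal(b$q[2], 2L)                                  # bin [0.02, 0.04)
  expect_true(all(b$q[-2] == 0L))

  # two events inside one bin: quanta sum and the bin is flagged
  s2 <- quantal_series(c(0.031, 0.038), c(1L, 2L))
  b2 <- bin_events(s2, p, bin_width = 0.02)
  expect_equal(b2$q[2], 3L)
  expect_true(b2$flagged[2])
  expect_equal(attr(b2, "violation_rate"), 0.1)

  expect_error(bin_events(s, p, bin_width = 0.03), "does not divide")
})

test_that("distribution estimation matches a hand-worked 2x2 table", {
  # 2 stimuli x 10 bins each; response alphabet {0, 1}
  p <- make_stimulus(c(20, 80), repeats = 1, randomize = FALSE)
  # stimulus 20: 2 bins with one quantum; stimulus 80: 5 bins with one quantum
  t20 <- c(0.005, 0.025)
  t80 <- 0.2 + c(0.005, 0.025, 0.045, 0.065, 0.085)
  s <- quantal_series(c(t20, t80), rep(1L, 7))
  d <- estimate_distributions(bin_events(s, p, 0.02), p)
  expect_equal(unname(d$p_q_given_s["20", ]), c(0.8, 0.2))
  expect_equal(unname(d$p_q_given_s["80", ]), c(0.5, 0.5))
  expect_equal(unname(d$p_s), c(0.5, 0.5))
  expect_equal(unname(d$p_sq["20", ]), c(0.4, 0.1))       # Eq. p(S,Q)=p(Q|S)p(S)
  expect_equal(unname(d$p_q), c(0.65, 0.35))
  expect_equal(unname(d$p_s_given_q[, 2]), c(0.1, 0.25) / 0.35)
  # all distributions normalized
  expect_equal(rowSums(d$p_q_given_s), c("20" = 1, "80" = 1))
  expect_equal(sum(d$p_sq), 1)
  expect_equal(colSums(d$p_s_given_q), c(1, 1), ignore_attr = TRUE)
})

test_that("degenerate single-contrast data stay normalized", {
  p <- make_stimulus(60, repeats = 3, randomize = FALSE)
  s <- quantal_series(numeric(0), integer(0))
  d <- estimate_distributions(bin_events(s, p, 0.02), p)
  expect_equal(unname(d$p_q_given_s[1, 1]), 1)
  expect_equal(sum(d$p_sq), 1)
})

test_that("mutual information: independence, bijection, binary symmetric channel", {
  # independent response: zero bits
  ind <- info_distributions(matrix(rep(c(0.7, 0.3), 4), 4, 2, byrow = TRUE),
                            rep(0.25, 4))
  expect_equal(mutual_information(ind), 0, tolerance = 1e-12)

  # deterministic bijection over 11 equiprobable stimuli: log2(11) bits
  bij <- info_distributions(diag(11), rep(1 / 11, 11))
  expect_equal(mutual_information(bij), log2(11), tolerance = 1e-12)
  expect_equal(round(mutual_information(bij), 2), 3.46)

  # binary symmetric channel, flip 0.25: 1 - Hb(0.25) bits
  bsc <- info_distributions(rbind(c(0.75, 0.25), c(0.25, 0.75)), c(0.5, 0.5))
  hb <- -(0.25 * log2(0.25) + 0.75 * log2(0.75))
  expect_equal(mutual_information(bsc), 1 - hb, tolerance = 1e-12)
})

test_that("specific information: deterministic, uninformative, decomposition identity", {
  bij <- info_distributions(diag(11), rep(1 / 11, 11))
  i2 <- specific_information(bij)
  expect_equal(i2$I2_bits, rep(log2(11), 11), tolerance = 1e-12)

  ind <- info_distributions(matrix(rep(c(0.6, 0.4), 3), 3, 2, byrow = TRUE),
                            rep(1 / 3, 3))
  expect_equal(specific_information(ind)$I2_bits, c(0, 0), tolerance = 1e-12)

  # p(q)-weighted mean of I2 equals the mutual information, on random tables
  for (seed in 1:100) {
    ch <- random_channel(4, 4, seed)
    set.seed(seed + 1e4)
    ps <- rexp(4); ps <- ps / sum(ps)
    d <- info_distributions(ch, ps)
    i2 <- specific_information(d)
    expect_equal(sum(i2$p_q * i2$I2_bits), mutual_information(d),
                 tolerance = 1e-9)
  }
})

test_that("plug-in mutual information matches the brute-force oracle on random tables", {
  for (seed in 1:50) {
    ch <- random_channel(4, 4, seed)
    set.seed(seed + 2e4)
    ps <- rexp(4); ps <- ps / sum(ps)
    expect_equal(mutual_information(info_distributions(ch, ps)),
                 mi_oracle(ch, ps), tolerance = 1e-9)
  }
})

test_that("information respects its bounds and coarse-graining never increases it", {
  for (seed in 1:30) {
    ch <- random_channel(5, 6, seed)
    ps <- rep(1 / 5, 5)
    d <- info_distributions(ch, ps)
    i <- mutual_information(d)
    ents <- info_entropies(d)
    expect_gte(i, -1e-12)
    expect_lte(i, min(ents["H_S"], ents["H_Q"]) + 1e-12)
    # merge the last two response symbols
    merged <- cbind(ch[, 1:4], ch[, 5] + ch[, 6])
    expect_lte(mutual_information(info_distributions(merged, ps)), i + 1e-12)
  }
})

test_that("the plug-in estimate converges to the true channel information", {
  ch <- rbind(c(0.8, 0.15, 0.05),
              c(0.3, 0.40, 0.30),
              c(0.05, 0.15, 0.8))
  ps <- rep(1 / 3, 3)
  true_i <- mi_oracle(ch, ps)
  bias <- vapply(c(100, 1000, 10000), function(n) {
    est <- vapply(1:10, function(r) {
      set.seed(n + r)
      s <- sample(1:3, n, replace = TRUE)
      q <- vapply(s, function(si) sample(1:3, 1, prob = ch[si, ]), numeric(1))
      tab <- table(factor(s, levels = 1:3), factor(q, levels = 1:3))
      emp <- sweep(unclass(tab), 1, pmax(rowSums(tab), 1), "/")
      mutual_information(info_distributions(emp, ps))
    }, numeric(1))
    abs(mean(est) - true_i)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))       # |bias| shrinks with sample size
  expect_gt(bias[1], bias[3])
})

test_that("information rate scales per-cycle bits by the stimulus frequency", {
  expect_equal(information_rate(log2(11), 5), 17.3, tolerance = 0.01)
  expect_equal(information_rate(0, 5), 0)
  expect_equal(information_rate(1, 10), 10)
})

test_that("the full information report runs on simulated data, both aggregations", {
  p <- standard_protocol(repeats = 10, seed = 2)
  s <- simulate_release(p, standard_model(), seed = 3)
  rep1 <- information_report(s, p)
  expect_equal(rep1$H_S, log2(11), tolerance = 1e-9)
  expect_equal(rep1$I_bits_per_cycle, rep1$I_bits_per_bin * 10)
  expect_equal(rep1$I_bits_per_s, rep1$I_bits_per_cycle * 5)
  expect_true(all(rep1$specific$p_q > 0))
  rep2 <- information_report(s, p, aggregation = "cycle_symbol")
  expect_gte(rep2$I_bits_per_cycle, 0)
  expect_lte(rep2$I_bits_per_cycle, log2(11) + 1e-9)
})

test_that("shuffling stimulus labels collapses information toward zero", {
  p <- standard_protocol(repeats = 10, seed = 5)
  s <- simulate_release(p, standard_model(), seed = 6)
  b <- bin_events(s, p)
  i_real <- mutual_information(estimate_distributions(b, p))
  null <- shuffle_null_information(b, p, n_shuffles = 10, seed = 1)
  expect_lt(null[["I_shuffled_mean"]], i_real)
})
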