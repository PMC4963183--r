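test_that("shift grid is symmetric, contains zero, has 2.5 ms steps", {
  g <- shift_grid()
  expect_equal(length(g), 81)
  expect_equal(g[41], 0)
  expect_equal(sort(-g), sort(g))
  expect_equal(diff(g)[1], 0.0025)
  expect_error(shift_grid(0.1, 0), "invalid")
})

test_that("LFP template fitting estimates the mean and the noise scale", {
  fs <- 2000; ext_len <- round(0.95 * fs)   # N = 1500 window samples
  tmpl <- random_template(ext_len)
  set.seed(41)
  mk <- function(j, noise) lapply(1:10, function(i)
    fake_aligned(tmpl + rnorm(ext_len, 0, noise), j = j, fs = fs))
  trials <- c(mk(1, 1), mk(2, 1))
  m <- fit_lfp_templates(trials)
  expect_lt(abs(m$sigma[1] - 1) / 1, 0.05)
  expect_gt(sqrt(sum((m$mu[[1]] - m$mu[[2]])^2)), 0)  # independent noise

  # identical trials: sigma floored, not zero
  same <- lapply(1:3, function(i) fake_aligned(tmpl, j = 1, fs = fs))
  m0 <- fit_lfp_templates(same)
  expect_equal(m0$sigma[1], 1e-9)
  expect_equal(m0$mu[[1]], same[[1]]$lfp)

  expect_error(fit_lfp_templates(same[1]), ">= 2 trials")
})

test_that("LFP log-likelihood matches its closed form and the direct oracle", {
  mu <- rnorm(50)
  expect_equal(lfp_loglik(mu, mu, 1), 0)
  e1 <- mu; e1[1] <- e1[1] + 1
  expect_equal(lfp_loglik(e1, mu, 1), -0.5)
  expect_error(lfp_loglik(mu[1:10], mu, 1), "length")

  set.seed(42)
  for (i in 1:100) {
    N <- sample(10:80, 1)
    v <- rnorm(N); m <- rnorm(N); s <- runif(1, 0.2, 3)
    expect_lt(abs(lfp_loglik(v, m, s) - oracle_lfp_loglik(v, m, s)), 1e-9)
  }
})

test_that("shift-invariant LFP classification finds the right template and lag", {
  fs <- 1000; N <- 750; pad <- 100
  set.seed(43)
  mus <- lapply(1:6, function(j) random_template(N))
  model <- structure(list(mu = mus, sigma = rep(1, 6), N = N, fs = fs),
                     class = "lfp_template_model")

  # noiseless trace equal to template 3 placed 50 ms late
  k <- round(0.05 * fs)
  v_ext <- numeric(N + 2 * pad)
  v_ext[(pad + k + 1):(pad + k + N)] <- mus[[3]]
  res <- classify_lfp(v_ext, model, shift_grid())
  expect_equal(res$j, 3)
  expect_equal(res$tau, 0.05)

  # degenerate grid {0} reduces to fixed-time classification
  v0 <- numeric(N + 2 * pad)
  v0[(pad + 1):(pad + N)] <- mus[[5]]
  res0 <- classify_lfp(v0, model, 0)
  expect_equal(res0$j, 5)
  expect_equal(res0$tau, 0)

  # grid-aligned shifts are recovered exactly (shift consistency)
  for (tau0 in c(-0.1, -0.0025, 0, 0.0025, 0.075)) {
    k0 <- round(tau0 * fs)
    v <- numeric(N + 2 * pad)
    v[(pad + k0 + 1):(pad + k0 + N)] <- mus[[2]]
    r <- classify_lfp(v, model, shift_grid())
    expect_equal(r$j, 2)
    expect_equal(r$tau, tau0)
  }
  expect_error(classify_lfp(numeric(N), model, shift_grid()), "short|incompatible")
})

test_that("vectorised LFP classification agrees with the exhaustive oracle", {
  fs <- 400; N <- 300; pad <- 40
  grid <- shift_grid(0.1, 0.0025)
  set.seed(44)
  for (rep in 1:20) {
    mus <- lapply(1:6, function(j) rnorm(N))
    model <- structure(list(mu = mus, sigma = runif(6, 0.5, 2), N = N, fs = fs),
                       class = "lfp_template_model")
    v_ext <- rnorm(N + 2 * pad)
    got <- classify_lfp(v_ext, model, grid)
    want <- oracle_classify_lfp(v_ext, model, grid)
    expect_equal(got$j, want$j)
    expect_equal(got$tau, want$tau)
  }
})

test_that("spike model probabilities follow the occupancy fractions with floor and cap", {
  # a bin occupied in every trial is capped just below 1
  trains <- replicate(28, c(0.010), simplify = FALSE)
  m <- fit_spike_model(trains, bin_width = 0.003, spontaneous_rate = 2)
  expect_equal(m$N, 250)
  expect_equal(m$p[4], 1 - 1e-6)           # 0.010 s is in bin 4
  # a never-occupied bin sits at the spontaneous floor 2 * 0.003
  expect_equal(m$p[10], 0.006)
  expect_error(fit_spike_model(trains, bin_width = 0), "positive")

  # homogeneous Poisson occupancy ~ 1 - exp(-lambda * dt)
  set.seed(45)
  lambda <- 40
  n_tr <- 2000
  trains2 <- replicate(n_tr, {
    n <- rpois(1, lambda * 0.75); sort(runif(n, 0, 0.75))
  }, simplify = FALSE)
  m2 <- fit_spike_model(trains2, spontaneous_rate = 0)
  p_true <- 1 - exp(-lambda * 0.003)
  se <- sqrt(p_true * (1 - p_true) / n_tr)
  expect_lt(abs(mean(m2$p) - p_true), 0.01)
  expect_lt(max(abs(m2$p - p_true)), 5 * se)
})

test_that("spike log-likelihood matches closed forms and the brute-force oracle", {
  m <- structure(list(p = rep(0.5, 4), bin_width = 0.1875, T = 0.75, N = 4,
                      p_min = 0), class = "spike_prob_model")
  expect_equal(spike_loglik(numeric(0), m), 4 * log(0.5))
  expect_equal(spike_loglik(c(0.05, 0.2, 0.4, 0.6), m), 4 * log(0.5))
  expect_error(spike_loglik(c(0.8), m), "outside")
  expect_error(spike_loglik(c(-0.1), m), "outside")

  set.seed(46)
  for (i in 1:100) {
    N <- sample(5:40, 1)
    T <- runif(1, 0.3, 1)
    p <- runif(N, 0.01, 0.99)
    mm <- structure(list(p = p, bin_width = T / N, T = T, N = N, p_min = 0),
                    class = "spike_prob_model")
    st <- runif(sample(0:10, 1), 0, T * 0.999)
    expect_lt(abs(spike_loglik(st, mm) - oracle_spike_loglik(st, p, T)), 1e-9)
  }
})

test_that("shift-invariant spike classification recovers condition and lag", {
  # deterministic PSTHs: condition j fires in a distinct block of bins
  # firing blocks are 120 ms apart, farther than the 100 ms shift span, so
  # no foreign condition can be reached by any lag
  T <- 0.75; N <- 250; bw <- T / N
  models <- lapply(1:6, function(j) {
    p <- rep(0.002, N)
    p[(40 * (j - 1) + 5):(40 * (j - 1) + 15)] <- 0.95
    structure(list(p = p, bin_width = bw, T = T, N = N, p_min = 0.002),
              class = "spike_prob_model")
  })
  st <- (seq(40 * 1 + 5, 40 * 1 + 15) - 0.5) * bw  # exactly condition 2's block
  res <- classify_spikes(st, models, shift_grid())
  expect_equal(res$j, 2)
  expect_equal(res$tau, 0)

  # the same train translated by +50 ms is recovered at tau = +0.05
  res_sh <- classify_spikes(st + 0.05, models, shift_grid())
  expect_equal(res_sh$j, 2)
  expect_equal(res_sh$tau, 0.05)

  # degenerate grid reduces to fixed-time rule
  res0 <- classify_spikes(st, models, 0)
  expect_equal(res0$j, 2)

  # oracle agreement on random instances
  set.seed(47)
  grid <- shift_grid(0.05, 0.01)
  for (rep in 1:15) {
    mods <- lapply(1:6, function(j) {
      p <- pmin(pmax(runif(50, 0, 0.4), 0.001), 0.999)
      structure(list(p = p, bin_width = 0.75 / 50, T = 0.75, N = 50,
                     p_min = 0.001), class = "spike_prob_model")
    })
    st_r <- runif(sample(1:15, 1), -0.05, 0.8)
    got <- classify_spikes(st_r, mods, grid)
    want <- oracle_classify_spikes(st_r, mods, grid)
    expect_equal(got$j, want$j)
    expect_equal(got$tau, want$tau)
  }
})

test_that("leave-one-out cross-validation is perfect on noiseless distinct trials", {
  fs <- 1000; N <- 750
  set.seed(48)
  mus <- lapply(1:6, function(j) random_template(N))
  aligned <- list()
  for (j in 1:6) for (r in 1:2) {
    v_ext <- numeric(N + 200)
    v_ext[101:(100 + N)] <- mus[[j]]
    aligned[[length(aligned) + 1]] <- fake_aligned(v_ext, j = j, fs = fs,
                                                   id = length(aligned) + 1)
  }
  res <- loocv(aligned, "lfp")
  expect_equal(res$accuracy, 1)
  expect_equal(unname(res$confusion), diag(6))
  expect_equal(rowSums(res$confusion), setNames(rep(1, 6), conditions()$label))

  expect_error(loocv(aligned[c(1, 3, 5)], "lfp"), ">= 2 trials")
})

test_that("confusion matrix rows are distributions and accuracy is their weighted diagonal", {
  p <- synth_params(n_trials_per_condition = 4, fs = 1000, seed = 49)
  d <- simulate_dataset(p)
  al <- align_dataset(d)
  res <- loocv(al$aligned, "spikes")
  expect_equal(unname(rowSums(res$confusion)), rep(1, 6), tolerance = 1e-9)
  js <- vapply(al$aligned, function(a) a$condition$j, integer(1))
  wts <- tabulate(js, 6) / length(js)
  expect_equal(res$accuracy, sum(diag(res$confusion) * wts), tolerance = 1e-12)
  expect_true(all(res$trials$predicted %in% 1:6))
})

test_that("rank-sum comparison of per-site accuracies behaves at the extremes", {
  expect_equal(compare_accuracies(rep(0.8, 5), rep(0.8, 5)), 1)
  set.seed(50)
  hi <- runif(15, 0.85, 0.95); lo <- runif(15, 0.05, 0.15)
  expect_lt(compare_accuracies(hi, lo), 0.001)
  expect_error(compare_accuracies(1, c(1, 2)), "equal-length")
})
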