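test_that("single-species batch reaches the logistic fixed point -r/a11", {
  p <- glv_params(r = 0.7, A = matrix(-0.7e-8, 1, 1), species = "sp1")
  final <- integrate_batch(p, 1e4, days = 80)
  expect_equal(unname(final), 1e8, tolerance = 1e-3)
})

test_that("negligible dynamics leave densities unchanged", {
  # zero growth with vanishing self-limitation: identity to machine precision
  p <- glv_params(r = c(0, 0), A = diag(c(-1e-24, -1e-24)),
                  species = c("a", "b"))
  final <- integrate_batch(p, c(1e6, 3e5), days = 7)
  expect_equal(unname(final), c(1e6, 3e5), tolerance = 1e-9)
})

test_that("two-species batch matches a fine-step Euler oracle within 0.5%", {
  p <- two_species_params()
  n0 <- c(2e6, 5e6)
  final <- integrate_batch(p, n0, days = 7)
  oracle <- euler_glv(p$r, p$A, n0, days = 7)
  expect_equal(unname(final), unname(oracle), tolerance = 5e-3)
})

test_that("parameter and input validation rejects bad values", {
  expect_error(glv_params(r = 0.5, A = matrix(0.1, 1, 1)), "negative")
  expect_error(glv_params(r = Inf, A = matrix(-1, 1, 1)), "finite")
  B <- array(0, dim = c(2, 2, 2)); B[1, 1, 2] <- 1e-18
  expect_error(glv_params(r = c(1, 1), A = -diag(2), B = B), "symmetric")
  p <- two_species_params()
  expect_error(integrate_batch(p, c(-1, 1e5), 7), ">= 0")
  expect_error(integrate_batch(p, c(1e5, 1e5), 0), "positive")
  expect_error(batch_protocol(dilution = 1), "exceed 1")
  expect_error(noise_model(log_sd = -0.1), ">= 0")
})

test_that("serial transfer dilutes then regrows, with extinction absorbing", {
  p <- glv_params(r = 1.5, A = matrix(-1.5 / 5e8, 1, 1), species = "mono")
  prot <- batch_protocol(batch_days = 7, dilution = 100, n_transfers = 4,
                         inoculum = 5e8)
  traj <- simulate_serial_transfer(p, prot)
  expect_equal(nrow(traj), 5)
  expect_equal(traj["0", "mono"], 5e8)
  # started at equilibrium: every post-transfer batch returns to it
  expect_true(all(abs(traj[-1, "mono"] / 5e8 - 1) < 0.01))
  # each row reproduces a manual dilute-and-integrate step
  manual <- integrate_batch(p, traj["1", ] / 100, 7)
  expect_equal(unname(traj["2", ]), unname(manual))
  # zero transfers returns the inoculum only
  traj0 <- simulate_serial_transfer(p, batch_protocol(n_transfers = 0,
                                                      inoculum = 1e5))
  expect_equal(nrow(traj0), 1)
  expect_equal(unname(traj0[1, ]), 1e5)
})

test_that("an excluded species stays extinct across transfers", {
  # strong asymmetric competition drives species 2 extinct
  p <- glv_params(r = c(1, 0.9),
                  A = rbind(c(-1 / 5e8, -0.1 * 1 / 5e8),
                            c(-3 * 0.9 / 5e8, -0.9 / 5e8)),
                  species = c("winner", "loser"))
  prot <- batch_protocol(batch_days = 14, n_transfers = 6, inoculum = 1e6)
  traj <- simulate_serial_transfer(p, prot)
  gone <- which(traj[, "loser"] == 0)
  expect_true(length(gone) > 0)
  expect_true(all(traj[gone[1]:nrow(traj), "loser"] == 0))
  expect_true(all(traj >= 0))
})

test_that("count noise is deterministic under a seed and unbiased on the log scale", {
  nm0 <- noise_model(log_sd = 0, detection_limit = 1)
  x <- c(0, 10, 1e4, 2.5e7)
  expect_identical(apply_count_noise(x, nm0), x)

  nm <- noise_model(log_sd = 0.2, seed = 99)
  expect_identical(apply_count_noise(x, nm), apply_count_noise(x, nm))
  expect_identical(apply_count_noise(x, nm)[1], 0)

  # lognormal mean identity: E[X] = mu * exp(log_sd^2 / 2)
  nm2 <- noise_model(log_sd = 0.1, seed = 7)
  draws <- apply_count_noise(rep(1e6, 1e4), nm2)
  expect_equal(mean(draws), 1e6 * exp(0.005), tolerance = 0.01)
})

test_that("densities below the detection limit are censored to zero", {
  nm <- noise_model(log_sd = 0, detection_limit = 100)
  expect_equal(apply_count_noise(c(50, 200, 0), nm), c(0, 200, 0))
  expect_error(apply_count_noise(c(-5, 10), nm), ">= 0")
})

test_that("study datasets have the design-implied shapes and determinism", {
  study <- generate_study_datasets(seed = 11, replicates = list(invasion = 2))
  expect_equal(nrow(unique(study$invasion[, c("focal", "residents")])), 75)
  expect_equal(nrow(study$persistence),
               sum(lengths(enumerate_compositions(default_pool()))) * 3 * 3)
  expect_true(all(study$persistence$density >= 0))
  expect_true(all(study$invasion$n1 >= 0))
  # per-species supernatant sources: fresh + 5 species, 3 technical reps
  expect_equal(nrow(study$supernatant), 5 * 6 * 3)

  again <- generate_study_datasets(seed = 11, replicates = list(invasion = 2))
  expect_identical(study$persistence, again$persistence)
  expect_identical(study$invasion, again$invasion)
  expect_identical(study$supernatant, again$supernatant)

  other <- generate_study_datasets(seed = 12, replicates = list(invasion = 2),
                                   assays = "invasion")
  expect_false(identical(study$invasion, other$invasion))
})

test_that("a no-interaction null yields pairwise w near 1 everywhere", {
  r <- c(1, 1.1, 0.9); K <- c(5e8, 4e8, 6e8)
  p <- glv_params(r, diag(-r / K), species = c("s1", "s2", "s3"))
  study <- generate_study_datasets(params = p, noise = noise_model(0.02),
                                   seed = 5, assays = "persistence")
  pw <- pairwise_matrix(study$persistence)
  expect_true(all(pw$w > 0.9 & pw$w < 1.1))
})

test_that("study tables round-trip through TSV", {
  study <- generate_study_datasets(seed = 3, assays = "invasion",
                                   replicates = list(invasion = 2))
  dir <- withr::local_tempdir()
  write_study_tsv(study, dir)
  back <- read_assay_tsv(file.path(dir, "invasion.tsv"))
  expect_equal(back, study$invasion, tolerance = 1e-12)
})
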