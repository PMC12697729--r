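test_that("forward process has the closed-form Gaussian marginal", {
  x0 <- matrix(rnorm(30), 10, 3)
  expect_equal(forward_noise(x0, 0, x0 * 0), x0)
  set.seed(1)
  draws <- replicate(1e4, forward_noise(0, 2, rnorm(1)))
  expect_equal(var(draws), 4, tolerance = 0.05)
  # Gaussian additivity: t then s equals one step at sqrt(t^2 + s^2)
  set.seed(2)
  two_step <- forward_noise(forward_noise(rep(0, 1e4), 2, rnorm(1e4)), 1.5, rnorm(1e4))
  expect_equal(var(two_step), 2^2 + 1.5^2, tolerance = 0.2)
})

test_that("training noise levels follow the log-normal with mu -1.2, sd 1.5", {
  cfg <- diffusion_config()
  set.seed(3)
  t <- sample_training_noise_level(1e5, cfg)
  expect_equal(median(t), cfg$sigma_data * exp(-1.2), tolerance = 0.03)
  expect_equal(sd(log(t / cfg$sigma_data)), 1.5, tolerance = 0.02)
  expect_equal(mean(log(t / cfg$sigma_data)), -1.2, tolerance = 0.03)
})

test_that("preconditioning scalings behave as specified", {
  cfg <- diffusion_config()
  zero_core <- function(x, cn, z) x * 0
  x <- rnorm(5)
  # c_skip -> 1 as t -> 0
  expect_equal(precondition(zero_core, x, 1e-6, cfg = cfg), x, tolerance = 1e-9)
  # at t = sigma_data, c_skip = 1/2
  expect_equal(precondition(zero_core, x, cfg$sigma_data, cfg = cfg), x / 2)
  expect_error(precondition(zero_core, x, 0), "t must be > 0")
  # a core built from the exact Gaussian posterior mean makes the
  # preconditioned denoiser the Bayes denoiser
  mu0 <- 3; sd0 <- 2
  core <- function(xs, cn, z) {
    t <- exp(4 * cn)
    xx <- xs * sqrt(cfg$sigma_data^2 + t^2)
    bayes <- (sd0^2 * xx + t^2 * mu0) / (sd0^2 + t^2)
    (bayes - cfg$sigma_data^2 / (cfg$sigma_data^2 + t^2) * xx) /
      (t * cfg$sigma_data / sqrt(cfg$sigma_data^2 + t^2))
  }
  for (t in c(0.1, 2.5, 40))
    expect_equal(precondition(core, x, t, cfg = cfg),
                 gaussian_denoiser(mu0, sd0)(x, t), tolerance = 1e-10)
  # c_in keeps the denoiser input near unit variance for sigma_data-scaled data
  set.seed(4)
  x0 <- rnorm(1e4, sd = cfg$sigma_data)
  t <- 10
  xt <- forward_noise(x0, t, rnorm(1e4))
  expect_equal(var(xt / sqrt(cfg$sigma_data^2 + t^2)), 1, tolerance = 0.05)
})

test_that("loss weighting has the EDM shape", {
  cfg <- diffusion_config()
  expect_equal(loss_weight(cfg$sigma_data), 2 / cfg$sigma_data^2)
  expect_error(loss_weight(0), "t must be > 0")
  grid <- exp(seq(log(1e-3), log(1e4), length.out = 60))
  w <- loss_weight(grid)
  expect_true(all(diff(w) < 0))                     # strictly decreasing
  expect_equal(w[length(w)], 1 / cfg$sigma_data^2, tolerance = 1e-5)
  expect_gt(loss_weight(1e-8), 1e10)                # diverges at 0
})

test_that("rigid alignment recovers rotations, rejects reflections, is idempotent", {
  set.seed(5)
  p <- matrix(rnorm(45), 15, 3)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- binderkit:::quat_to_rot(q)
  fit <- rigid_align(p %*% R + 7, p)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # mirror image cannot be superposed with a proper rotation
  mirror <- p; mirror[, 1] <- -mirror[, 1]
  fit_m <- rigid_align(mirror, p)
  expect_equal(det(fit_m$rotation), 1, tolerance = 1e-9)
  expect_gt(fit_m$rmsd, 0.1)
  # brute-force check: the best of many random proper rotations never beats it
  best <- min(replicate(200, {
    qq <- rnorm(4); qq <- qq / sqrt(sum(qq^2))
    m <- mirror %*% binderkit:::quat_to_rot(qq)
    sqrt(mean(rowSums((scale(m, scale = FALSE) - scale(p, scale = FALSE))^2)))
  }))
  expect_gte(best, fit_m$rmsd - 1e-6)
  # idempotent
  again <- rigid_align(fit$coords, p)
  expect_lt(max(abs(again$coords - fit$coords)), 1e-9)
})

test_that("MSE loss removes rigid motion and applies the 11:1 ligand weighting", {
  set.seed(6)
  x <- matrix(rnorm(30), 10, 3)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  expect_equal(mse_loss(x, x %*% binderkit:::quat_to_rot(q) + 3), 0, tolerance = 1e-12)
  # one displaced ligand atom vs one displaced protein atom: ratio 11
  cls <- rep("protein", 10)
  bump <- function(classes, i) {
    y <- x; y[i, 1] <- y[i, 1] + 1
    mse_loss(y, x, atom_classes = classes, align = FALSE)
  }
  cls_lig <- cls; cls_lig[4] <- "ligand"
  expect_equal(bump(cls_lig, 4) / bump(cls, 4), 11)
  cls_nuc <- cls; cls_nuc[4] <- "rna"
  expect_equal(bump(cls_nuc, 4) / bump(cls, 4), 6)
  expect_gte(mse_loss(x + rnorm(30), x), 0)
  expect_error(mse_loss(x, x, atom_classes = rep("steel", 10)), "unknown atom class")
})

test_that("bond loss measures length error only and ignores rigid motion", {
  x <- matrix(c(0, 0, 0, 1.5, 0, 0, 3, 0, 0), 3, 3, byrow = TRUE)
  bonds <- cbind(c(1, 2), c(2, 3))
  expect_equal(bond_loss(x, x, bonds), 0)
  stretched <- x; stretched[3, 1] <- stretched[3, 1] + 0.5
  expect_equal(bond_loss(stretched, x, cbind(2, 3)), 0.25)
  set.seed(7)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  expect_equal(bond_loss(x %*% binderkit:::quat_to_rot(q) + 5, x, bonds), 0,
               tolerance = 1e-12)
  expect_equal(bond_loss(x, x, matrix(numeric(0), 0, 2)), 0)
})

test_that("smooth lDDT is minimal at truth, rigid-invariant, monotone in noise", {
  h <- make_ideal_helix(8)
  x <- coords(h)
  base <- smooth_lddt_loss(x, x)
  set.seed(8)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  expect_equal(smooth_lddt_loss(x %*% binderkit:::quat_to_rot(q) + 2, x), base,
               tolerance = 1e-9)
  losses <- vapply(c(0.1, 0.5, 1, 2), function(sd) {
    set.seed(9)
    smooth_lddt_loss(x + matrix(rnorm(length(x), sd = sd), nrow(x), 3), x)
  }, numeric(1))
  expect_true(all(diff(c(base, losses)) > 0))
})

test_that("total loss composes its parts under the t-dependent weight", {
  h <- make_ideal_helix(6)
  x0 <- coords(h)
  set.seed(10)
  pred <- x0 + matrix(rnorm(length(x0), sd = 0.3), nrow(x0), 3)
  bonds <- cbind(seq_len(nrow(x0) - 1), seq_len(nrow(x0) - 1) + 1)
  t <- 2.5
  out <- total_loss(pred, x0, t, bonds = bonds)
  expect_equal(out$total, out$weight * (out$mse + out$bond + out$smooth_lddt))
  expect_equal(out$weight, loss_weight(t))
  perfect <- total_loss(x0, x0, t, bonds = bonds)
  expect_equal(perfect$mse, 0, tolerance = 1e-12)
  expect_equal(perfect$bond, 0, tolerance = 1e-12)
})

test_that("the noise schedule hits its endpoints and is strictly decreasing", {
  cfg <- diffusion_config()
  sch <- make_schedule(cfg)
  expect_length(as.numeric(sch), 300L)
  expect_equal(sch[1], cfg$sigma_data * cfg$s_max)
  expect_equal(sch[length(sch)], cfg$sigma_data * cfg$s_min)
  expect_true(all(diff(as.numeric(sch)) < 0))
  for (n in c(10, 77)) {
    s <- make_schedule(diffusion_config(n_steps = n), dilation_config())
    expect_length(as.numeric(s), n)
    expect_true(all(diff(as.numeric(s)) < 0))
  }
})

test_that("the dilated time map is the documented continuous bijection", {
  cfg <- dilation_config()
  expect_equal(cfg$r, (1 - (8 / 3) * 0.2) / 0.8)
  expect_equal(dilate(0, cfg), 0)
  expect_equal(dilate(1, cfg), 1)
  expect_equal(dilate(0.35, cfg), 0.6)   # l = r * tau_s maps to tau_s
  expect_equal(dilate(cfg$u, cfg), 0.8)
  g <- seq(0, 1, by = 1e-3)
  expect_lt(max(abs(dilate(dilate(g, cfg), cfg, inverse = TRUE) - g)), 1e-12)
  expect_true(all(diff(dilate(g, cfg)) > 0))
  expect_error(dilation_config(lambda = 6), "lambda")
  expect_error(dilation_config(lambda = 1), "lambda")
})

test_that("uniform steps land lambda-times denser inside the dilated window", {
  sch <- make_schedule(diffusion_config(), dilation_config())
  tau <- attr(sch, "tau")
  frac <- mean(tau >= 0.6 & tau <= 0.8)
  expect_equal(frac, (8 / 3) * 0.2, tolerance = 2 / 300)
})

test_that("the sampler is seed-deterministic and aborts on non-finite denoisers", {
  den <- gaussian_denoiser(0, 1)
  sch <- make_schedule(diffusion_config(n_steps = 40))
  x1 <- edm_sample(den, sch, shape = c(50, 3), seed = 21)
  x2 <- edm_sample(den, sch, shape = c(50, 3), seed = 21)
  expect_identical(x1, x2)
  expect_equal(dim(x1), c(50L, 3L))
  bad <- function(x, t, z) { x[1] <- NaN; x }
  expect_error(edm_sample(bad, sch, shape = c(5, 3), seed = 1), "step 1")
})

test_that("with no re-noising and a near-point data distribution the sampler collapses to the mean", {
  den <- gaussian_denoiser(mean = -4, sd = 1e-3)
  x <- edm_sample(den, make_schedule(), shape = c(500, 1), seed = 2, beta = 0)
  expect_equal(mean(x), -4, tolerance = 1e-2)
  expect_lt(sd(as.numeric(x)), 0.05)
})
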