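# EDM diffusion mathematics: forward process, preconditioned denoiser
# contract, training losses, noise schedules (including the dilated time
# map), and the stochastic sampler. Everything is denoiser-agnostic so the
# whole layer can be exercised with analytic denoisers.

#' Diffusion configuration
#'
#' Scale and schedule constants of the variance-exploding diffusion process
#' `X_t = X_0 + t * eps`. The defaults are the values used for all-atom
#' biomolecular coordinates in Angstrom: `sigma_data = 16`,
#' `s_min = 4e-4`, `s_max = 160`, schedule exponent `rho = 7`, 300 sampling
#' steps, and a log-normal training-noise distribution
#' `t = sigma_data * exp(-1.2 + 1.5 * N(0,1))`.
#'
#' @param sigma_data data scale (Angstrom).
#' @param s_min,s_max relative noise bounds of the schedule.
#' @param rho schedule exponent.
#' @param n_steps number of denoiser evaluations in the schedule.
#' @param noise_mu,noise_sd log-space location/scale of the training noise
#'   distribution.
#' @return object of class `bk_diffusion_config`.
#' @export
diffusion_config <- function(sigma_data = 16, s_min = 4e-4, s_max = 160,
                             rho = 7, n_steps = 300,
                             noise_mu = -1.2, noise_sd = 1.5) {
  if (sigma_data <= 0) stop("sigma_data must be > 0")
  if (s_min >= s_max) stop("s_min must be < s_max")
  if (n_steps < 2) stop("n_steps must be >= 2")
  structure(list(sigma_data = sigma_data, s_min = s_min, s_max = s_max,
                 rho = rho, n_steps = as.integer(n_steps),
                 noise_mu = noise_mu, noise_sd = noise_sd),
            class = "bk_diffusion_config")
}

#' Dilated-schedule configuration
#'
#' Parameters of the piecewise-linear time map that stretches the interval
#' `[tau_s, tau_e]` of the schedule by a factor `lambda`, concentrating
#' denoiser evaluations in the window where residue identities are resolved.
#' Requires `1 < lambda < 1 / (tau_e - tau_s)`.
#'
#' @param lambda dilation factor (default 8/3).
#' @param tau_s,tau_e dilated interval on the schedule time axis
#'   (defaults 0.6 and 0.8).
#' @return object of class `bk_dilation_config` carrying the derived branch
#'   constants `r`, `l`, `u`.
#' @export
dilation_config <- function(lambda = 8 / 3, tau_s = 0.6, tau_e = 0.8) {
  if (!(tau_s >= 0 && tau_s < tau_e && tau_e <= 1))
    stop("need 0 <= tau_s < tau_e <= 1")
  width <- tau_e - tau_s
  if (!(lambda > 1 && lambda < 1 / width))
    stop("lambda must lie in (1, 1/(tau_e - tau_s))")
  r <- (1 - lambda * width) / (1 - width)
  l <- r * tau_s
  u <- l + lambda * width
  structure(list(lambda = lambda, tau_s = tau_s, tau_e = tau_e,
                 r = r, l = l, u = u),
            class = "bk_dilation_config")
}

#' Dilating time map
#'
#' Continuous piecewise-linear bijection of `[0, 1]` whose middle branch has
#' slope `1/lambda`, so that uniformly spaced steps passed through the map
#' land `lambda` times more densely inside `[tau_s, tau_e]`. The outer
#' branches have slope `1/r`; the map satisfies `phi(0) = 0`, `phi(1) = 1`,
#' `phi(l) = tau_s` and `phi(u) = tau_e`.
#'
#' @param tau numeric vector in `[0, 1]`.
#' @param cfg a [dilation_config()].
#' @param inverse apply the inverse map.
#' @return mapped values in `[0, 1]`.
#' @export
dilate <- function(tau, cfg = dilation_config(), inverse = FALSE) {
  if (any(tau < -1e-12 | tau > 1 + 1e-12)) stop("tau must lie in [0, 1]")
  tau <- pmin(pmax(tau, 0), 1)
  if (inverse) {
    ifelse(tau < cfg$tau_s, tau * cfg$r,
           ifelse(tau > cfg$tau_e, (tau - cfg$tau_e) * cfg$r + cfg$u,
                  (tau - cfg$tau_s) * cfg$lambda + cfg$l))
  } else {
    ifelse(tau < cfg$l, tau / cfg$r,
           ifelse(tau > cfg$u, (tau - cfg$u) / cfg$r + cfg$tau_e,
                  (tau - cfg$l) / cfg$lambda + cfg$tau_s))
  }
}

#' Build the sampling noise schedule
#'
#' Computes the strictly decreasing noise levels
#' `t_i = sigma_data * (s_max^(1/rho) + tau_i * (s_min^(1/rho) - s_max^(1/rho)))^rho`
#' with `tau_i` uniform on `[0, 1]` over `n_steps` points, optionally passed
#' through the dilating time map first.
#'
#' @param cfg a [diffusion_config()].
#' @param dilation optional [dilation_config()]; NULL gives the plain
#'   schedule.
#' @return object of class `bk_schedule`: numeric vector of noise levels,
#'   with the (mapped) `tau` grid as an attribute.
#' @examples
#' sch <- make_schedule()
#' length(sch)           # 300
#' head(as.numeric(sch)) # starts at sigma_data * s_max
#' @export
make_schedule <- function(cfg = diffusion_config(), dilation = NULL) {
  tau <- seq(0, 1, length.out = cfg$n_steps)
  if (!is.null(dilation)) {
    if (!inherits(dilation, "bk_dilation_config"))
      stop("dilation must be a dilation_config()")
    tau <- dilate(tau, dilation)
  }
  t <- cfg$sigma_data *
    (cfg$s_max^(1 / cfg$rho) + tau * (cfg$s_min^(1 / cfg$rho) - cfg$s_max^(1 / cfg$rho)))^cfg$rho
  if (any(diff(t) >= 0)) stop("schedule is not strictly decreasing")
  structure(t, tau = tau, class = c("bk_schedule", "numeric"))
}

#' Forward diffusion: noise clean coordinates to level t
#'
#' The variance-exploding forward process has marginal
#' `X_t = X_0 + t * eps` with `eps ~ N(0, I)`.
#'
#' @param x0 clean coordinates (vector or matrix).
#' @param t noise level (>= 0).
#' @param eps standard-normal draw of the same shape as `x0`; drawn
#'   internally when NULL.
#' @return noisy coordinates, same shape as `x0`.
#' @export
forward_noise <- function(x0, t, eps = NULL) {
  if (t < 0) stop("t must be >= 0")
  if (is.null(eps)) eps <- array(stats::rnorm(length(x0)), dim = dim(x0) %||% length(x0))
  if (length(eps) != length(x0)) stop("eps shape must match x0")
  x0 + t * eps
}

#' Sample training noise levels
#'
#' Draws from the log-normal training distribution
#' `t = sigma_data * exp(noise_mu + noise_sd * N(0, 1))`.
#'
#' @param n number of draws.
#' @param cfg a [diffusion_config()].
#' @return numeric vector of noise levels.
#' @export
sample_training_noise_level <- function(n = 1, cfg = diffusion_config()) {
  cfg$sigma_data * exp(cfg$noise_mu + cfg$noise_sd * stats::rnorm(n))
}

#' EDM preconditioning of a raw denoising core
#'
#' Wraps a raw network/oracle `F` into the denoiser
#' `D(x, t) = c_skip * x + c_out * F(c_in * x, c_noise; z)` with
#' `c_skip = sd^2 / (sd^2 + t^2)`, `c_out = t * sd / sqrt(sd^2 + t^2)`,
#' `c_in = 1 / sqrt(sd^2 + t^2)`, `c_noise = log(t) / 4`, so that the core
#' sees unit-variance inputs and targets.
#'
#' @param core function `(x_scaled, c_noise, z)` returning an array shaped
#'   like `x_scaled`.
#' @param x noisy coordinates.
#' @param t noise level (> 0).
#' @param z optional conditioning passed through to `core`.
#' @param cfg a [diffusion_config()].
#' @return denoised coordinates, same shape as `x`.
#' @export
precondition <- function(core, x, t, z = NULL, cfg = diffusion_config()) {
  if (t <= 0) stop("precondition: t must be > 0")
  sd2 <- cfg$sigma_data^2
  c_skip <- sd2 / (sd2 + t^2)
  c_out <- t * cfg$sigma_data / sqrt(sd2 + t^2)
  c_in <- 1 / sqrt(sd2 + t^2)
  c_noise <- log(t) / 4
  f <- core(c_in * x, c_noise, z)
  if (length(f) != length(x)) stop("precondition: core output shape mismatch")
  c_skip * x + c_out * f
}

#' EDM loss weighting
#'
#' `w(t) = (t^2 + sigma_data^2) / (t * sigma_data)^2`; diverges as `t -> 0`
#' and asymptotes to `1 / sigma_data^2` for large `t`.
#'
#' @param t noise level(s), > 0.
#' @param cfg a [diffusion_config()].
#' @export
loss_weight <- function(t, cfg = diffusion_config()) {
  if (any(t <= 0)) stop("loss_weight: t must be > 0")
  (t^2 + cfg$sigma_data^2) / (t * cfg$sigma_data)^2
}

#' Atom-class weights for the coordinate loss
#'
#' Protein atoms weigh 1, nucleic-acid atoms 6, ligand atoms 11.
#' @param atom_classes character vector with entries `"protein"`,
#'   `"nucleic"` (or `"dna"`/`"rna"`), `"ligand"`.
#' @return numeric weights.
#' @export
atom_class_weights <- function(atom_classes) {
  w <- c(protein = 1, nucleic = 6, dna = 6, rna = 6, ligand = 11)[atom_classes]
  if (any(is.na(w)))
    stop("unknown atom class: ",
         paste(unique(atom_classes[is.na(w)]), collapse = ", "))
  unname(w)
}

#' Aligned, class-weighted coordinate MSE loss
#'
#' The target is first rigidly superposed onto the prediction (weighted by
#' the atom-class weights), then
#' `L = (1/3) * sum_l w_l * ||pred_l - target_aligned_l||^2`.
#'
#' @param pred,target n x 3 coordinate matrices.
#' @param atom_classes per-atom class labels (see [atom_class_weights()]).
#' @param align superpose target onto pred first (default TRUE).
#' @return non-negative scalar.
#' @export
mse_loss <- function(pred, target, atom_classes = NULL, align = TRUE) {
  pred <- as_coord_matrix(pred); target <- as_coord_matrix(target)
  if (nrow(pred) != nrow(target)) stop("mse_loss: shape mismatch")
  w <- if (is.null(atom_classes)) rep(1, nrow(pred)) else atom_class_weights(atom_classes)
  if (align && nrow(pred) >= 3L) target <- rigid_align(target, pred, weights = w)$coords
  sum(w * rowSums((pred - target)^2)) / 3
}

#' Bond-length loss
#'
#' Mean squared difference between predicted and target bond lengths over
#' the bond list; invariant to rigid motion of either structure.
#'
#' @param pred,target_aligned n x 3 coordinate matrices.
#' @param bonds data.frame/matrix with two columns of atom indices; an empty
#'   bond set gives 0.
#' @export
bond_loss <- function(pred, target_aligned, bonds) {
  pred <- as_coord_matrix(pred); target_aligned <- as_coord_matrix(target_aligned)
  bonds <- as.matrix(bonds)
  if (!nrow(bonds)) return(0)
  if (any(bonds < 1) || any(bonds > nrow(pred)))
    stop("bond_loss: bonds reference invalid atoms")
  dp <- sqrt(rowSums((pred[bonds[, 1], , drop = FALSE] - pred[bonds[, 2], , drop = FALSE])^2))
  dt <- sqrt(rowSums((target_aligned[bonds[, 1], , drop = FALSE] -
                        target_aligned[bonds[, 2], , drop = FALSE])^2))
  mean((dp - dt)^2)
}

#' Smooth lDDT surrogate loss
#'
#' Differentiable local-distance-difference test: for atom pairs within the
#' inclusion radius in the target, distance errors are scored with sigmoids
#' at the 0.5, 1, 2 and 4 Angstrom thresholds; the loss is one minus the
#' mean score. Superposition-free, so invariant to rigid motion of either
#' input.
#'
#' @param pred,target n x 3 coordinate matrices.
#' @param inclusion_radius pair inclusion radius in the target (Angstrom);
#'   use 30 for nucleic acids.
#' @param thresholds distance-difference thresholds (Angstrom).
#' @param temperature sigmoid temperature.
#' @return loss in `[0, 1)`, minimal when `pred == target`.
#' @export
smooth_lddt_loss <- function(pred, target, inclusion_radius = 15,
                             thresholds = c(0.5, 1, 2, 4), temperature = 1) {
  pred <- as_coord_matrix(pred); target <- as_coord_matrix(target)
  if (nrow(pred) != nrow(target)) stop("smooth_lddt_loss: shape mismatch")
  n <- nrow(pred)
  if (n < 2L) return(0)
  dt <- as.matrix(stats::dist(target))
  dp <- as.matrix(stats::dist(pred))
  inc <- upper.tri(dt) & dt < inclusion_radius
  if (!any(inc)) return(0)
  delta <- abs(dp[inc] - dt[inc])
  score <- rowMeans(vapply(thresholds,
                           function(th) stats::plogis((th - delta) / temperature),
                           numeric(sum(inc))))
  1 - mean(score)
}

#' Total training loss
#'
#' `w(t) * (L_MSE + L_bond + L_smooth_lDDT)`.
#'
#' @param pred denoiser output, n x 3.
#' @param x0 clean target coordinates, n x 3.
#' @param t noise level (> 0).
#' @param bonds bond index pairs for [bond_loss()] (may be empty).
#' @param atom_classes per-atom class labels.
#' @param cfg a [diffusion_config()].
#' @return list with `total` and the components `mse`, `bond`,
#'   `smooth_lddt`, `weight`.
#' @export
total_loss <- function(pred, x0, t, bonds = NULL,
                       atom_classes = NULL, cfg = diffusion_config()) {
  pred <- as_coord_matrix(pred); x0 <- as_coord_matrix(x0)
  w <- if (is.null(atom_classes)) rep(1, nrow(pred)) else atom_class_weights(atom_classes)
  aligned <- if (nrow(pred) >= 3L) rigid_align(x0, pred, weights = w)$coords else x0
  l_mse <- mse_loss(pred, aligned, atom_classes, align = FALSE)
  l_bond <- if (is.null(bonds) || !NROW(bonds)) 0 else bond_loss(pred, aligned, bonds)
  l_lddt <- smooth_lddt_loss(pred, x0)
  wt <- loss_weight(t, cfg)
  list(total = wt * (l_mse + l_bond + l_lddt),
       mse = l_mse, bond = l_bond, smooth_lddt = l_lddt, weight = wt)
}

#' Analytic Gaussian denoiser
#'
#' For data `X_0 ~ N(mean, sd^2)` (independently per coordinate) under the
#' forward process `X_t = X_0 + t * eps`, the exact posterior mean is
#' `(sd^2 * x + t^2 * mean) / (sd^2 + t^2)`. Useful as a ground-truth
#' denoiser for sampler validation.
#'
#' @param mean,sd data distribution parameters.
#' @return denoiser function `(x, t, z)`.
#' @export
gaussian_denoiser <- function(mean = 0, sd = 1) {
  force(mean); force(sd)
  function(x, t, z = NULL) (sd^2 * x + t^2 * mean) / (sd^2 + t^2)
}

#' Stochastic EDM sampler
#'
#' Starts from `x ~ N(0, t_1^2)` and, at each step, injects noise scaled by
#' `beta` to climb to an elevated level, evaluates the denoiser there, and
#' steps toward the prediction with step scale `alpha` (a second-order Heun
#' correction is applied by default). `alpha = beta = 1` is the standard
#' sampler; larger `alpha` or smaller `beta` trades diversity for
#' designability. Deterministic given the seed: noise draws are consumed in
#' a fixed order (initialisation first, then one injection per step).
#'
#' @param denoiser function `(x, t, z)` returning the posterior-mean
#'   estimate, same shape as `x`.
#' @param schedule a [make_schedule()] result (or decreasing numeric vector).
#' @param shape output shape, e.g. `c(n_atoms, 3)`.
#' @param alpha step scale (> 0).
#' @param beta noise scale (>= 0).
#' @param churn per-step noise-injection factor gamma; the elevated level is
#'   `sqrt(t^2 + beta^2 * ((1 + churn)^2 - 1) * t^2)`.
#' @param seed RNG seed; NULL uses the current RNG state.
#' @param z optional conditioning forwarded to the denoiser.
#' @param second_order apply the Heun corrector step.
#' @return array of dimension `shape` with the sampled coordinates.
#' @examples
#' den <- gaussian_denoiser(mean = 2, sd = 1)
#' x <- edm_sample(den, make_schedule(), shape = c(1000, 1), seed = 7)
#' c(mean(x), var(as.numeric(x)))  # close to (2, 1)
#' @export
edm_sample <- function(denoiser, schedule, shape, alpha = 1, beta = 1,
                       churn = 0.4, seed = NULL, z = NULL,
                       second_order = TRUE) {
  t <- as.numeric(schedule)
  if (length(t) < 2L || any(diff(t) >= 0)) stop("schedule must be strictly decreasing")
  if (alpha <= 0) stop("alpha must be > 0")
  if (beta < 0) stop("beta must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- prod(shape)
  x <- stats::rnorm(n) * t[1]
  for (i in seq_len(length(t) - 1L)) {
    ti <- t[i]; tn <- t[i + 1]
    inj_sd <- beta * sqrt((ti * (1 + churn))^2 - ti^2)
    x <- x + stats::rnorm(n) * inj_sd
    th <- sqrt(ti^2 + inj_sd^2)      # actual level after injection
    xh <- denoiser(array(x, dim = shape), th, z)
    if (any(!is.finite(xh)))
      stop(sprintf("edm_sample: denoiser returned non-finite values at step %d", i))
    xh <- as.numeric(xh)
    d1 <- (x - xh) / th
    xe <- x + alpha * (tn - th) * d1
    if (second_order && tn > 0) {
      x2 <- denoiser(array(xe, dim = shape), tn, z)
      if (any(!is.finite(x2)))
        stop(sprintf("edm_sample: denoiser returned non-finite values at step %d", i))
      d2 <- (xe - as.numeric(x2)) / tn
      x <- x + alpha * (tn - th) * (d1 + d2) / 2
    } else {
      x <- xe
    }
  }
  array(x, dim = shape)
}
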