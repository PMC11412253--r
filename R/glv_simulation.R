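#' Generalized Lotka-Volterra community parameters
#'
#' Ground-truth parameters for the batch-culture community simulator:
#' per-species intrinsic growth rates `r` (day^-1), a per-capita
#' interaction matrix `A` with `a_ij` the effect of species j on the
#' per-capita growth of species i ((cfu/mL)^-1 day^-1), and an optional
#' higher-order tensor `B` whose entry `b_ijk` multiplies the product
#' `N_j * N_k` ((cfu/mL)^-2 day^-1). Self-limitation requires
#' `a_ii < 0`; `B` must be symmetric in its last two indices with zero
#' `(j, j)` diagonal slices.
#'
#' @param r Numeric vector of intrinsic growth rates (day^-1).
#' @param A Square interaction matrix, `length(r)` on a side.
#' @param B Optional 3-d array `n x n x n` of higher-order coefficients;
#'   `NULL` (the default) means purely pairwise dynamics.
#' @param species Species labels; defaults to `names(r)`.
#' @return Object of class `glv_params`.
#' @export
glv_params <- function(r, A, B = NULL, species = names(r)) {
  n <- length(r)
  if (n < 1 || !is.numeric(r) || any(!is.finite(r))) {
    stop("r must be a nonempty finite numeric vector", call. = FALSE)
  }
  if (is.null(species)) species <- paste0("sp", seq_len(n))
  species <- validate_pool(species)
  if (length(species) != n) stop("species labels must match length(r)", call. = FALSE)
  A <- as.matrix(A)
  if (!all(dim(A) == c(n, n)) || any(!is.finite(A))) {
    stop("A must be a finite ", n, "x", n, " matrix", call. = FALSE)
  }
  if (any(diag(A) >= 0)) {
    stop("all self-interaction terms a_ii must be negative (self-limitation)",
         call. = FALSE)
  }
  if (!is.null(B)) {
    if (!is.array(B) || !all(dim(B) == c(n, n, n)) || any(!is.finite(B))) {
      stop("B must be a finite ", n, "x", n, "x", n, " array", call. = FALSE)
    }
    for (i in seq_len(n)) {
      sl <- B[i, , ]
      if (any(abs(sl - t(sl)) > 0)) {
        stop("B must be symmetric in its (j, k) indices", call. = FALSE)
      }
      if (any(diag(sl) != 0)) {
        stop("B must have zero (j, j) diagonal entries", call. = FALSE)
      }
    }
  }
  names(r) <- species
  dimnames(A) <- list(species, species)
  if (!is.null(B)) dimnames(B) <- list(species, species, species)
  structure(list(r = r, A = A, B = B, species = species),
            class = "glv_params")
}

#' @export
print.glv_params <- function(x, ...) {
  cat("gLV community parameters:", length(x$species), "species\n")
  cat("  r (day^-1):", paste(signif(x$r, 3), collapse = ", "), "\n")
  cat("  higher-order terms:", if (is.null(x$B)) "none" else "present", "\n")
  invisible(x)
}

#' Serial-transfer batch protocol
#'
#' Describes the weekly-transfer culture regime: batch duration, the
#' transfer dilution factor (1:100 weekly in the reference protocol),
#' the number of transfers, and per-species inoculation densities.
#'
#' @param batch_days Days per batch (default 7).
#' @param dilution Transfer dilution factor (default 100, i.e. 1%
#'   carried over each week).
#' @param n_transfers Number of serial transfers (default 4).
#' @param inoculum Per-species starting densities (cfu/mL); a scalar is
#'   recycled over the community.
#' @return Object of class `batch_protocol`.
#' @export
batch_protocol <- function(batch_days = 7, dilution = 100, n_transfers = 4,
                           inoculum = 3e6) {
  if (!is.numeric(batch_days) || batch_days <= 0) {
    stop("batch_days must be positive", call. = FALSE)
  }
  if (!is.numeric(dilution) || dilution <= 1) {
    stop("dilution factor must exceed 1", call. = FALSE)
  }
  if (n_transfers < 0) stop("n_transfers must be >= 0", call. = FALSE)
  if (any(inoculum < 0)) stop("inoculum densities must be >= 0", call. = FALSE)
  structure(list(batch_days = batch_days, dilution = dilution,
                 n_transfers = as.integer(n_transfers), inoculum = inoculum),
            class = "batch_protocol")
}

#' Plate-count noise model
#'
#' Multiplicative lognormal measurement error for colony counts:
#' each positive density is multiplied by `exp(e)` with
#' `e ~ Normal(0, log_sd)` on the natural-log scale; results below the
#' detection limit are reported as 0 (a plate count cannot distinguish
#' absence from below-detection).
#'
#' @param log_sd Standard deviation of the log-scale error (default 0.1,
#'   roughly a 10% coefficient of variation typical of plate counts).
#' @param detection_limit Smallest reportable density (cfu/mL, default 1).
#' @param seed Optional RNG seed giving reproducible draws.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(log_sd = 0.1, detection_limit = 1, seed = NULL) {
  if (!is.numeric(log_sd) || log_sd < 0) stop("log_sd must be >= 0", call. = FALSE)
  if (!is.numeric(detection_limit) || detection_limit <= 0) {
    stop("detection_limit must be positive", call. = FALSE)
  }
  structure(list(log_sd = log_sd, detection_limit = detection_limit,
                 seed = seed),
            class = "noise_model")
}

glv_derivative <- function(params) {
  r <- unname(params$r)
  A <- unname(params$A)
  B <- params$B
  n <- length(r)
  function(t, N, parms) {
    N <- pmax(N, 0)
    per_capita <- r + as.vector(A %*% N)
    if (!is.null(B)) {
      # sum_{j<k} b_ijk N_j N_k = 0.5 * N' B_i N (zero diagonal, symmetric)
      for (i in seq_len(n)) {
        per_capita[i] <- per_capita[i] + 0.5 * drop(crossprod(N, B[i, , ] %*% N))
      }
    }
    list(N * per_capita)
  }
}

#' Integrate one batch of community growth
#'
#' Numerically integrates the generalized Lotka-Volterra batch dynamics
#' `dN_i/dt = N_i (r_i + sum_j a_ij N_j + sum_{j<k} b_ijk N_j N_k)`
#' over one closed batch (no dilution). Densities are kept nonnegative;
#' species ending below the extinction threshold are set to exactly 0,
#' making extinction reproducible.
#'
#' @param params A [glv_params()] object.
#' @param n0 Nonnegative per-species starting densities (cfu/mL), in
#'   pool order.
#' @param days Batch duration (days, > 0).
#' @param extinction_threshold Density below which a species is scored
#'   extinct (default 1e-3 cfu/mL).
#' @param rtol Relative integration tolerance (default 1e-8).
#' @param trajectory If `TRUE`, also return the full time course.
#' @return Named numeric vector of final densities; with
#'   `trajectory = TRUE`, a list with elements `final` and `trajectory`.
#' @export
#' @examples
#' p <- glv_params(r = 0.7, A = matrix(-0.7e-8, 1, 1), species = "sp1")
#' integrate_batch(p, 1e4, days = 60) # approaches -r/a11 = 1e8
integrate_batch <- function(params, n0, days, extinction_threshold = 1e-3,
                            rtol = 1e-8, trajectory = FALSE) {
  stopifnot(inherits(params, "glv_params"))
  n <- length(params$r)
  if (length(n0) != n) stop("n0 must have one density per species", call. = FALSE)
  if (any(!is.finite(n0)) || any(n0 < 0)) {
    stop("initial densities must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(days) || days <= 0) stop("days must be positive", call. = FALSE)
  times <- if (trajectory) seq(0, days, length.out = 201) else c(0, days)
  sol <- deSolve::ode(y = unname(n0), times = times, func = glv_derivative(params),
                      parms = NULL, rtol = rtol, atol = 1e-6 * extinction_threshold)
  final <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
  final[final < extinction_threshold] <- 0
  names(final) <- params$species
  if (trajectory) {
    traj <- as.data.frame(sol)
    names(traj) <- c("time", params$species)
    list(final = final, trajectory = traj)
  } else {
    final
  }
}

#' Simulate serial-transfer dynamics
#'
#' Runs repeated batch culture: each transfer divides the community
#' densities by the protocol's dilution factor and integrates one batch.
#' A species at density 0 stays at 0 (extinction is absorbing).
#'
#' @param params A [glv_params()] object.
#' @param protocol A [batch_protocol()] object.
#' @param composition Character vector of species present at inoculation
#'   (default: the whole pool).
#' @param ... Passed on to [integrate_batch()].
#' @return Numeric matrix with one column per species and one row per
#'   transfer; row `"0"` is the inoculum and row `t` the end-of-batch
#'   densities after transfer `t`.
#' @export
simulate_serial_transfer <- function(params, protocol,
                                     composition = params$species, ...) {
  stopifnot(inherits(params, "glv_params"), inherits(protocol, "batch_protocol"))
  if (!all(composition %in% params$species)) {
    stop("composition members must belong to the parameterised pool",
         call. = FALSE)
  }
  n <- length(params$species)
  inoc <- rep_len(protocol$inoculum, n)
  n0 <- numeric(n)
  names(n0) <- params$species
  n0[composition] <- inoc[match(composition, params$species)]
  out <- matrix(NA_real_, nrow = protocol$n_transfers + 1L, ncol = n,
                dimnames = list(0:protocol$n_transfers, params$species))
  out[1, ] <- n0
  N <- n0
  for (tr in seq_len(protocol$n_transfers)) {
    N <- integrate_batch(params, N / protocol$dilution, protocol$batch_days, ...)
    out[tr + 1L, ] <- N
  }
  out
}

#' Apply plate-count noise to densities
#'
#' Multiplies each positive density by lognormal error and censors
#' values below the detection limit to 0. Zero densities pass through
#' unchanged. When the noise model carries a seed the draw is
#' reproducible and the caller's RNG state is left untouched.
#'
#' @param densities Nonnegative numeric vector of true densities.
#' @param noise A [noise_model()] object.
#' @return Numeric vector of noisy, detection-censored densities.
#' @export
apply_count_noise <- function(densities, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (any(densities < 0)) stop("densities must be >= 0", call. = FALSE)
  if (!is.null(noise$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(noise$seed)
  }
  out <- densities
  pos <- densities > 0
  if (any(pos)) {
    out[pos] <- densities[pos] * exp(rnorm(sum(pos), 0, noise$log_sd))
  }
  out[out < noise$detection_limit & out > 0] <- 0
  out
}

#' Reference five-species community parameters
#'
#' A coexisting five-species parameter set used as simulator ground
#' truth. Intrinsic rates are nearly equal (an equalising mechanism:
#' dilute complex medium narrows fitness differences), intraspecific
#' competition exceeds interspecific competition (a stabilising
#' mechanism: relative interaction coefficients of 0.15-0.30), and
#' *Variovorax* receives facilitation (negative coefficients) from three
#' community members while competing with *Stenotrophomonas*, mirroring
#' the asymmetric positive interactions seen in such communities. The
#' set is feasible (all equilibrium densities positive) and mutually
#' invasible: every species has a positive growth rate when rare against
#' every resident subset.
#'
#' @param hoi_strength Magnitude of engineered higher-order terms; 0
#'   (the default) gives purely pairwise dynamics, 1 gives suppressive
#'   product-form terms `b_ijk` (for partner pairs j, k both different
#'   from the focal i) whose contribution at typical community densities
#'   matches the mean pairwise off-diagonal effect. The terms are
#'   negative: suppressive higher-order effects keep batch dynamics
#'   bounded, whereas positive product terms can outrun the linear
#'   self-limitation.
#' @return A [glv_params()] object for the five-species pool.
#' @export
community_glv_params <- function(hoi_strength = 0) {
  species <- default_pool()
  r <- c(1.00, 1.02, 1.08, 0.98, 0.95)
  K <- c(5e8, 6e8, 8e8, 4e8, 3e8)
  # relative competition coefficients c_ij (effect of j on i, c_ii = 1)
  C <- rbind(
    c(1.00,  0.25,  0.30, 0.20, 0.20),
    c(0.20,  1.00,  0.30, 0.25, 0.20),
    c(0.25,  0.20,  1.00, 0.25, 0.30),
    c(0.22,  0.15,  0.20, 1.00, 0.20),
    c(-0.20, -0.25, -0.30, 0.25, 1.00)
  )
  A <- -C * (r / K)  # a_ij = -c_ij * r_i / K_i (row-wise scaling)
  B <- NULL
  if (hoi_strength != 0) {
    n <- length(r)
    B <- array(0, dim = c(n, n, n))
    n_ref <- 2.5e8  # typical equilibrium density scale
    for (i in seq_len(n)) {
      a_off <- mean(abs(A[i, -i]))
      for (j in seq_len(n - 1)) {
        for (k in (j + 1):n) {
          if (i == j || i == k) next
          b <- -hoi_strength * a_off / n_ref
          B[i, j, k] <- b
          B[i, k, j] <- b
        }
      }
    }
  }
  glv_params(r = r, A = A, B = B, species = species)
}

#' Reference supernatant-effect ground truth
#'
#' The spent-media (supernatant) effect matrix `sigma` used by the
#' simulator: `sigma[i, j]` multiplies the baseline daily growth rate of
#' focal species i when grown in the cell-free supernatant of species j.
#' Own supernatant is strongly depleted (diagonal well below the
#' interspecific entries, so intraspecific competition exceeds
#' interspecific competition), and *Variovorax* grows better than
#' baseline in three species' supernatants (cross-feeding). The matrix
#' is deliberately a separate ground truth from the co-culture
#' interaction matrix: diffusible-product effects need not match whole
#' co-culture outcomes.
#'
#' @param species Species labels (default [default_pool()]).
#' @return Numeric matrix with rows = focal species, columns = supernatant
#'   source.
#' @export
community_sigma <- function(species = default_pool()) {
  n <- length(species)
  if (n != 5) stop("the reference sigma matrix is defined for 5 species",
                   call. = FALSE)
  sigma <- rbind(
    c(0.12, 0.70, 0.55, 0.80, 0.65),
    c(0.75, 0.18, 0.60, 0.70, 0.80),
    c(0.60, 0.65, 0.25, 0.75, 0.70),
    c(0.70, 0.80, 0.55, 0.15, 0.60),
    c(1.15, 1.25, 1.10, 0.55, 0.08)
  )
  dimnames(sigma) <- list(species, species)
  sigma
}
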