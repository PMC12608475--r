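#' Configuration for synthetic swelling experiments
#'
#' Generates swelling data with the statistical structure the estimator
#' assumes: percent swelling declines linearly with the Hansen distance from
#' a known true polymer HSP, plus Gaussian noise, truncated at 0 (a sample
#' cannot de-swell below zero volume change in a good-solvent design; in
#' practice the truncation bites only for the poorest solvents). An optional
#' additive outlier on one named solvent mimics a reactive solvent whose
#' measured swelling does not reflect the unaltered polymer.
#'
#' @param true_hsp Ground-truth polymer HSP.
#' @param solvents Solvent table to simulate with, or an integer: that many
#'   solvents drawn (seeded) uniformly over delta_d in \[14, 20\], delta_p and
#'   delta_hb in \[0, 17\] -- the span of common laboratory solvents.
#' @param intercept Swelling at Ra = 0, percent (default 200, a strongly
#'   swelling best solvent).
#' @param slope Percent swelling lost per MPa^(1/2) of Ra (> 0; default 8,
#'   which takes swelling from the intercept to near zero across the typical
#'   0-25 MPa^(1/2) Ra span).
#' @param noise_sd Observation noise sd, percentage points.
#' @param n_replicates Replicate experiments to simulate.
#' @param outlier_solvent,outlier_offset Optional reactive-solvent outlier:
#'   name and additive percent-swelling offset.
#' @param seed Seed for solvent draws and noise.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(true_hsp, solvents = 8, intercept = 200,
                             slope = 8, noise_sd = 5, n_replicates = 1,
                             outlier_solvent = NULL, outlier_offset = 0,
                             seed = 1L) {
  true_hsp <- as_hsp(true_hsp)
  if (slope <= 0) stop("slope must be > 0 (swelling decreases with Ra)",
                       call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(true_hsp = true_hsp, solvents = solvents,
                 intercept = intercept, slope = slope, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 outlier_solvent = outlier_solvent,
                 outlier_offset = outlier_offset, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Seeded random solvent set spanning the common-solvent region of Hansen
# space.
random_solvent_table <- function(n, seed) {
  with_local_seed(seed, {
    data.frame(name = paste0("solvent_", seq_len(n)),
               delta_d = stats::runif(n, 14, 20),
               delta_p = stats::runif(n, 0, 17),
               delta_hb = stats::runif(n, 0, 17),
               source = "synthetic",
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic swelling dataset with known ground truth
#'
#' Draws swelling_i = max(0, intercept - slope * Ra(true_hsp, solvent_i) +
#' noise) per solvent and replicate, fully reproducible under the config's
#' seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `dataset` (a `"swelling_dataset"`), `solvents` (the
#'   solvent table used) and `truth` (true HSP plus generative parameters).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  solvents <- if (is.data.frame(config$solvents)) {
    validate_solvent_table(config$solvents)
  } else {
    random_solvent_table(as.integer(config$solvents), config$seed)
  }
  sm <- cbind(solvents$delta_d, solvents$delta_p, solvents$delta_hb)
  if (nrow(unique(sm)) < 2L) {
    stop("degenerate solvent set: all solvents identical", call. = FALSE)
  }
  truth <- as.numeric(config$true_hsp)
  ra <- as.vector(ra_matrix(matrix(truth, 1L, 3L), sm))
  clean <- config$intercept - config$slope * ra
  if (mean(clean) < 0) {
    stop("intercept too small: mean noiseless swelling is negative over ",
         "this solvent set", call. = FALSE)
  }

  obs <- with_local_seed(config$seed + 1L, {
    do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
      eps <- if (config$noise_sd > 0) {
        stats::rnorm(length(ra), 0, config$noise_sd)
      } else rep(0, length(ra))
      sw <- clean + eps
      if (!is.null(config$outlier_solvent)) {
        i <- match(config$outlier_solvent, solvents$name)
        if (is.na(i)) stop("outlier solvent '", config$outlier_solvent,
                           "' not in solvent set", call. = FALSE)
        sw[i] <- sw[i] + config$outlier_offset
      }
      data.frame(solvent = solvents$name, replicate = r,
                 percent_swelling = pmax(0, sw))
    }))
  })

  list(dataset = swelling_dataset(obs),
       solvents = solvents,
       truth = list(hsp = config$true_hsp, intercept = config$intercept,
                    slope = config$slope, noise_sd = config$noise_sd,
                    seed = config$seed))
}

#' Parameter-recovery study
#'
#' Repeatedly generates synthetic swelling data and re-estimates the HSP,
#' summarizing how well the true parameters are recovered under the given
#' design (solvent count, noise level). Estimation failures are counted and
#' reported, never silently dropped.
#'
#' @param config A [synthetic_config()]; its seed is replaced by
#'   `seed + 1 ... seed + n_seeds` across runs (fresh solvent draws and noise
#'   each run when `solvents` is a count).
#' @param n_seeds Number of independent runs (>= 10).
#' @param estimation Passed to [estimate_hsp()] as its config.
#' @param seed Base seed.
#' @return Object of class `"recovery_study"`: per-component `bias`, `rmse`,
#'   `median_abs_error`, plus `boundary_hit_rate`, `mean_plateau_size`,
#'   `n_failed`, and the per-run estimate matrix `estimates`.
#' @export
recovery_study <- function(config, n_seeds = 100,
                           estimation = estimation_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (n_seeds < 10) stop("n_seeds must be >= 10", call. = FALSE)
  truth <- as.numeric(config$true_hsp)
  est <- matrix(NA_real_, n_seeds, 3,
                dimnames = list(NULL, c("delta_d", "delta_p", "delta_hb")))
  boundary_hits <- 0L
  plateau_sizes <- integer(0)
  n_failed <- 0L
  failures <- character(0)
  for (k in seq_len(n_seeds)) {
    cfg_k <- config
    cfg_k$seed <- seed + k
    sim <- generate_dataset(cfg_k)
    fit <- try(suppressWarnings(
      estimate_hsp(sim$dataset, sim$solvents, estimation)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      n_failed <- n_failed + 1L
      failures <- c(failures, conditionMessage(attr(fit, "condition")))
      next
    }
    est[k, ] <- as.numeric(fit$hsp)
    if (any(fit$boundary_flags)) boundary_hits <- boundary_hits + 1L
    plateau_sizes <- c(plateau_sizes, nrow(fit$plateau))
  }
  err <- sweep(est, 2, truth)
  structure(list(
    truth = config$true_hsp,
    n_seeds = n_seeds,
    n_failed = n_failed,
    failure_messages = unique(failures),
    estimates = est,
    bias = colMeans(err, na.rm = TRUE),
    rmse = sqrt(colMeans(err^2, na.rm = TRUE)),
    median_abs_error = apply(abs(err), 2, stats::median, na.rm = TRUE),
    boundary_hit_rate = boundary_hits / max(1L, n_seeds - n_failed),
    mean_plateau_size = mean(plateau_sizes)
  ), class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  v <- as.numeric(x$truth)
  cat(sprintf("Recovery study: truth (%.1f, %.1f, %.1f), %d seeds, %d failed\n",
              v[1], v[2], v[3], x$n_seeds, x$n_failed))
  comp <- c("delta_d", "delta_p", "delta_hb")
  for (j in 1:3) {
    cat(sprintf("  %-8s bias %+6.2f  RMSE %5.2f  median |err| %5.2f\n",
                comp[j], x$bias[j], x$rmse[j], x$median_abs_error[j]))
  }
  cat(sprintf("  boundary-hit rate %.2f, mean plateau size %.1f\n",
              x$boundary_hit_rate, x$mean_plateau_size))
  invisible(x)
}
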