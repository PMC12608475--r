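#' Configuration for the constrained HSP estimator
#'
#' The estimator searches the box \[lower, upper\]^3 in Hansen space (default
#' 2.5 to 40 MPa^(1/2), the range covering the vast majority of substances)
#' with a deterministic coarse-to-fine grid, replacing manual trial-and-error
#' R-squared maximization with a reproducible search.
#'
#' @param lower,upper Box bounds per HSP component, MPa^(1/2).
#' @param coarse_step Coarse grid spacing, MPa^(1/2) (default 0.5).
#' @param refine_step Refinement grid spacing, MPa^(1/2) (default 0.05); the
#'   final optimum is resolved to this step.
#' @param plateau_tolerance Candidates whose R-squared is within this value of
#'   the optimum are reported as the near-optimal plateau (default 1e-6);
#'   exposes flat or degenerate directions of the objective.
#' @param multistart_count Number of seeded local continuous refinements
#'   (L-BFGS-B) from random starts, in addition to one started at the grid
#'   optimum; 0 (default) keeps the estimate purely grid-based.
#' @param seed Seed for the multistart draws.
#' @return An object of class `"estimation_config"`.
#' @export
estimation_config <- function(lower = 2.5, upper = 40,
                              coarse_step = 0.5, refine_step = 0.05,
                              plateau_tolerance = 1e-6,
                              multistart_count = 0, seed = 1L) {
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper) {
    stop("bounds must satisfy lower < upper", call. = FALSE)
  }
  if (coarse_step <= 0 || refine_step <= 0) {
    stop("grid steps must be > 0", call. = FALSE)
  }
  if (plateau_tolerance < 0) stop("plateau_tolerance must be >= 0",
                                  call. = FALSE)
  structure(list(lower = lower, upper = upper, coarse_step = coarse_step,
                 refine_step = refine_step,
                 plateau_tolerance = plateau_tolerance,
                 multistart_count = as.integer(multistart_count),
                 seed = as.integer(seed)),
            class = "estimation_config")
}

#' Signed R-squared objective for a candidate polymer HSP
#'
#' For a candidate HSP, computes Ra to each solvent and fits the ordinary
#' least-squares line of Ra on percent swelling. Because a good solvent
#' (low Ra) must swell the polymer more, the physically meaningful fits are
#' the negatively correlated ones: the score is +R-squared when the Pearson
#' correlation is negative and -R-squared when it is positive, so any
#' maximizer automatically rejects positively correlated candidates.
#'
#' @param candidate HSP vector for the polymer.
#' @param swelling_means Named numeric vector, percent swelling per solvent.
#' @param solvents Solvent HSP table covering all names in `swelling_means`.
#' @return Signed score in \[-1, 1\].
#' @export
objective_r2 <- function(candidate, swelling_means, solvents) {
  candidate <- as_hsp(candidate)
  if (length(swelling_means) < 3L) {
    stop("need at least 3 solvents to fit 3 HSP components", call. = FALSE)
  }
  if (length(swelling_means) < 5L) {
    warning("fewer than 5 solvents: the fit is weakly determined",
            call. = FALSE)
  }
  if (stats::sd(swelling_means) == 0) {
    stop("degenerate input: zero variance in swelling", call. = FALSE)
  }
  sm <- solvent_matrix(solvents, names(swelling_means))
  drop(signed_r2(matrix(as.numeric(candidate), 1L, 3L), sm,
                 as.numeric(swelling_means)))
}

# Solvent table -> m x 3 matrix in the order of `names`, validating coverage.
solvent_matrix <- function(solvents, names) {
  validate_solvent_table(solvents)
  i <- match(names, solvents$name)
  if (anyNA(i)) {
    stop("solvent(s) missing from table: ",
         paste(names[is.na(i)], collapse = ", "), call. = FALSE)
  }
  cbind(solvents$delta_d[i], solvents$delta_p[i], solvents$delta_hb[i])
}

# Vectorised signed R^2 over candidate rows. r is the Pearson correlation
# between the candidate's Ra profile and the swelling values; score is
# -sign(r) * r^2 so that negative correlation scores positively.
signed_r2 <- function(candidates, solvent_hsp, swelling) {
  R <- ra_matrix(candidates, solvent_hsp)
  sc <- swelling - mean(swelling)
  Rc <- R - rowMeans(R)
  denom <- sqrt(rowSums(Rc^2)) * sqrt(sum(sc^2))
  r <- as.vector(Rc %*% sc) / denom
  r[denom == 0] <- 0  # candidate equidistant from all solvents: no fit
  ifelse(r < 0, r^2, -r^2)
}

axis_grid <- function(lower, upper, step) {
  g <- seq(lower, upper, by = step)
  if (g[length(g)] < upper) g <- c(g, upper)
  g
}

#' Estimate a polymer's HSP from swelling data
#'
#' Inverse estimation for insoluble (cross-linked) polymers: finds the HSP
#' vector maximizing the R-squared of the linear Ra-vs-swelling relation
#' (negative correlations only) over the bounded cube. The search is a
#' deterministic coarse grid followed by a fine grid around the coarse
#' optimum; exact ties break to the lexicographically smallest
#' (delta_d, delta_p, delta_hb). Components that land exactly on a box bound
#' are flagged: a boundary solution signals limited identifiability from the
#' data, not a converged interior optimum.
#'
#' @param dataset A `"swelling_dataset"`; solvents flagged as excluded are
#'   removed before fitting.
#' @param solvents Solvent HSP table (default [hansen_solvents()]).
#' @param config An [estimation_config()].
#' @param replicate If given, fit only this replicate's observations;
#'   otherwise per-solvent replicate means are fitted.
#' @return An object of class `"hsp_estimate"` with elements `hsp`,
#'   `r_squared`, `slope_sign`, `boundary_flags`, `plateau` (matrix of
#'   near-optimal HSPs), `per_solvent_ra`, `residuals` (from the OLS line of
#'   Ra on swelling), `swelling` and `config`.
#' @export
estimate_hsp <- function(dataset, solvents = hansen_solvents(),
                         config = estimation_config(), replicate = NULL) {
  stopifnot(inherits(dataset, "swelling_dataset"),
            inherits(config, "estimation_config"))
  if (is.null(replicate)) {
    summ <- summarize_replicates(dataset, include_excluded = FALSE)
    sw <- stats::setNames(summ$mean, summ$solvent)
  } else {
    sw <- repetition_swelling(dataset, replicate)
  }
  if (length(sw) < 3L) {
    stop("need at least 3 non-excluded solvents, have ", length(sw),
         call. = FALSE)
  }
  if (length(sw) < 5L) {
    warning("fewer than 5 solvents: the fit is weakly determined",
            call. = FALSE)
  }
  if (stats::sd(sw) == 0) {
    stop("degenerate input: zero variance in swelling", call. = FALSE)
  }
  sm <- solvent_matrix(solvents, names(sw))
  swelling <- as.numeric(sw)

  # coarse pass over the full cube
  ax <- axis_grid(config$lower, config$upper, config$coarse_step)
  coarse <- as.matrix(expand.grid(delta_d = ax, delta_p = ax, delta_hb = ax,
                                  KEEP.OUT.ATTRS = FALSE))
  s_coarse <- signed_r2(coarse, sm, swelling)
  best_coarse <- pick_best(coarse, s_coarse)

  # fine pass on a cube of half-width coarse_step around the coarse optimum
  fine_ax <- function(center) {
    g <- seq(center - config$coarse_step, center + config$coarse_step,
             by = config$refine_step)
    unique(pmin(pmax(g, config$lower), config$upper))
  }
  fine <- as.matrix(expand.grid(delta_d = fine_ax(best_coarse[1]),
                                delta_p = fine_ax(best_coarse[2]),
                                delta_hb = fine_ax(best_coarse[3]),
                                KEEP.OUT.ATTRS = FALSE))
  s_fine <- signed_r2(fine, sm, swelling)
  best <- pick_best(fine, s_fine)
  best_score <- max(s_fine)

  # optional seeded multistart continuous refinement (off by default)
  if (config$multistart_count > 0L) {
    neg_obj <- function(x) -signed_r2(matrix(x, 1L, 3L), sm, swelling)
    starts <- rbind(best,
                    with_local_seed(config$seed, {
                      matrix(stats::runif(3L * config$multistart_count,
                                          config$lower, config$upper),
                             ncol = 3L)
                    }))
    for (k in seq_len(nrow(starts))) {
      o <- try(stats::optim(starts[k, ], neg_obj, method = "L-BFGS-B",
                            lower = config$lower, upper = config$upper),
               silent = TRUE)
      if (!inherits(o, "try-error") && -o$value > best_score) {
        best_score <- -o$value
        best <- o$par
      }
    }
  }

  if (best_score <= 0) {
    stop("estimation failed: every candidate in the search box is ",
         "positively correlated with swelling (best signed score ",
         signif(best_score, 4), "); check the swelling data and solvent table",
         call. = FALSE)
  }

  evaluated <- rbind(coarse, fine)
  scores <- c(s_coarse, s_fine)
  on_plateau <- scores >= best_score - config$plateau_tolerance
  plateau <- unique(evaluated[on_plateau, , drop = FALSE])

  ra <- as.vector(ra_matrix(matrix(best, 1L, 3L), sm))
  names(ra) <- names(sw)
  fit <- stats::lm(ra ~ swelling)

  structure(list(
    hsp = hsp(best[1], best[2], best[3]),
    r_squared = best_score,
    slope_sign = if (unname(stats::coef(fit)[2]) < 0) "negative" else "positive",
    boundary_flags = c(delta_d = best[1] %in% c(config$lower, config$upper),
                       delta_p = best[2] %in% c(config$lower, config$upper),
                       delta_hb = best[3] %in% c(config$lower, config$upper)),
    plateau = plateau,
    per_solvent_ra = ra,
    residuals = stats::setNames(stats::residuals(fit), names(sw)),
    swelling = sw,
    config = config
  ), class = "hsp_estimate")
}

# lexicographically smallest (delta_d, delta_p, delta_hb) among exact ties
pick_best <- function(candidates, scores) {
  top <- candidates[scores == max(scores), , drop = FALSE]
  unname(top[order(top[, 1], top[, 2], top[, 3])[1L], ])
}

#' @export
print.hsp_estimate <- function(x, ...) {
  cat("HSP estimate from swelling data\n")
  v <- as.numeric(x$hsp)
  flag <- ifelse(x$boundary_flags, " [on bound]", "")
  cat(sprintf("  delta_d  = %6.2f%s\n  delta_p  = %6.2f%s\n  delta_hb = %6.2f%s\n",
              v[1], flag[1], v[2], flag[2], v[3], flag[3]))
  cat(sprintf("  R-squared = %.4f (slope %s), %d solvent(s), plateau size %d\n",
              x$r_squared, x$slope_sign, length(x$swelling), nrow(x$plateau)))
  invisible(x)
}

#' Fit each repetition separately and average the fitted HSPs
#'
#' Replicate swelling experiments are fitted independently and the final
#' polymer HSP is the component-wise mean of the per-repetition estimates
#' (fits are averaged, data are not pooled, so between-repetition spread in
#' the fitted parameters stays visible).
#'
#' @param dataset A `"swelling_dataset"` containing all repetitions, or a
#'   list of single-repetition datasets.
#' @param solvents Solvent HSP table.
#' @param config An [estimation_config()].
#' @return A list of class `"hsp_estimate_set"`: `fits` (one `"hsp_estimate"`
#'   per repetition), `average` (mean HSP vector), `boundary_flags` (TRUE if
#'   flagged in every repetition).
#' @export
estimate_per_repetition <- function(dataset, solvents = hansen_solvents(),
                                    config = estimation_config()) {
  if (inherits(dataset, "swelling_dataset")) {
    reps <- sort(unique(dataset$observations$replicate))
    fits <- lapply(reps, function(r) {
      estimate_hsp(dataset, solvents, config, replicate = r)
    })
    names(fits) <- paste0("repetition_", reps)
  } else if (is.list(dataset) && length(dataset) &&
             all(vapply(dataset, inherits, logical(1), "swelling_dataset"))) {
    fits <- lapply(dataset, estimate_hsp, solvents = solvents, config = config)
    if (is.null(names(fits))) {
      names(fits) <- paste0("repetition_", seq_along(fits))
    }
  } else {
    stop("dataset must be a swelling_dataset or a list of them", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(fits, function(f) as.numeric(f$hsp)))
  avg <- colMeans(mat)
  flags <- Reduce(`&`, lapply(fits, `[[`, "boundary_flags"))
  structure(list(fits = fits,
                 average = hsp(avg[1], avg[2], avg[3]),
                 boundary_flags = flags),
            class = "hsp_estimate_set")
}

#' @export
print.hsp_estimate_set <- function(x, ...) {
  cat(sprintf("HSP estimates from %d repetition(s)\n", length(x$fits)))
  for (nm in names(x$fits)) {
    v <- as.numeric(x$fits[[nm]]$hsp)
    cat(sprintf("  %s: (%.2f, %.2f, %.2f)  R2 = %.4f\n", nm,
                v[1], v[2], v[3], x$fits[[nm]]$r_squared))
  }
  v <- as.numeric(x$average)
  cat(sprintf("  average: (%.2f, %.2f, %.2f)\n", v[1], v[2], v[3]))
  invisible(x)
}

# Run code under a temporary RNG state so callers' streams are untouched.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
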