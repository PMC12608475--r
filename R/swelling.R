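#' Volume of a rectangular slab sample from caliper dimensions
#'
#' Swelling samples are treated as rectangular slabs; irregular geometries
#' must be supplied as volumes directly.
#'
#' @param length,width,thickness Dimensions in a common unit (e.g. mm).
#' @return Volume in the cube of that unit.
#' @export
volume_from_dimensions <- function(length, width, thickness) {
  dims <- c(length, width, thickness)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("all dimensions must be finite and > 0", call. = FALSE)
  }
  length * width * thickness
}

#' Volumetric degree of swelling
#'
#' Percent swelling of an insoluble polymer after immersion,
#' 100 * (V_after - V_before) / V_before. The percent scale matches how
#' swelling tables are conventionally reported.
#'
#' @param v_before Dry volume before immersion (> 0).
#' @param v_after Volume after immersion (> 0).
#' @return Percent swelling (vectorised).
#' @export
percent_swelling <- function(v_before, v_after) {
  if (any(!is.finite(v_before)) || any(v_before <= 0)) {
    stop("v_before must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(v_after)) || any(v_after <= 0)) {
    stop("v_after must be finite and > 0", call. = FALSE)
  }
  100 * (v_after - v_before) / v_before
}

#' Assemble a swelling dataset
#'
#' One row per (solvent, replicate) observation, either as percent swelling
#' directly or as volumes before/after immersion. Solvents that chemically
#' alter the polymer during immersion (hydrolysis, transesterification) can
#' be flagged for exclusion so the estimator never sees them; the swelling
#' they produce does not refer to the same polymer structure as the inert
#' solvents.
#'
#' @param observations Data frame with columns `solvent`, `replicate`, and
#'   either `percent_swelling` or both `v_before` and `v_after`.
#' @param exclude Named character vector: names are solvent names, values are
#'   reason codes (`"chemical_alteration"` or `"user"`). An unnamed character
#'   vector is accepted and given reason `"user"`.
#' @return An object of class `"swelling_dataset"`.
#' @examples
#' obs <- data.frame(solvent = rep(c("hexane", "chloroform"), each = 2),
#'                   replicate = c(1, 2, 1, 2),
#'                   percent_swelling = c(12, 20, 175, 194))
#' swelling_dataset(obs)
#' @export
swelling_dataset <- function(observations, exclude = character()) {
  obs <- as.data.frame(observations)
  need <- c("solvent", "replicate")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(obs) == 0L) stop("empty swelling dataset", call. = FALSE)
  obs$solvent <- as.character(obs$solvent)

  if (!"percent_swelling" %in% names(obs)) {
    if (!all(c("v_before", "v_after") %in% names(obs))) {
      stop("need either percent_swelling or v_before and v_after columns",
           call. = FALSE)
    }
    obs$percent_swelling <- percent_swelling(obs$v_before, obs$v_after)
  }
  if (any(!is.finite(obs$percent_swelling)) ||
      any(obs$percent_swelling <= -100)) {
    stop("percent_swelling must be finite and > -100", call. = FALSE)
  }
  dup <- duplicated(obs[, c("solvent", "replicate")])
  if (any(dup)) {
    stop("duplicate replicate id(s) within solvent: ",
         paste(unique(obs$solvent[dup]), collapse = ", "), call. = FALSE)
  }

  if (length(exclude) && is.null(names(exclude))) {
    exclude <- stats::setNames(rep("user", length(exclude)), exclude)
  }
  ok_reasons <- c("chemical_alteration", "user")
  if (length(exclude) && !all(exclude %in% ok_reasons)) {
    stop("exclusion reasons must be one of: ",
         paste(ok_reasons, collapse = ", "), call. = FALSE)
  }

  structure(list(observations = obs, excluded = exclude),
            class = "swelling_dataset")
}

#' @export
print.swelling_dataset <- function(x, ...) {
  ns <- length(unique(x$observations$solvent))
  cat(sprintf("Swelling dataset: %d observations, %d solvents\n",
              nrow(x$observations), ns))
  if (length(x$excluded)) {
    cat("Excluded:", paste(sprintf("%s (%s)", names(x$excluded), x$excluded),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a swelling dataset from CSV
#'
#' Expected columns: `solvent`, `replicate`, and either `percent_swelling` or
#' `v_before`/`v_after`. An optional `exclude` column carries a reason code
#' (`chemical_alteration` or `user`) on any row of the excluded solvent.
#'
#' @param path Path to a CSV file with a header row.
#' @return A `"swelling_dataset"`.
#' @export
read_swelling <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  exclude <- character()
  if ("exclude" %in% names(obs)) {
    flagged <- obs[!is.na(obs$exclude) & nzchar(obs$exclude), ]
    if (nrow(flagged)) {
      exclude <- stats::setNames(flagged$exclude, flagged$solvent)
      exclude <- exclude[!duplicated(names(exclude))]
    }
    obs$exclude <- NULL
  }
  swelling_dataset(obs, exclude = exclude)
}

#' Per-solvent replicate summary
#'
#' Mean and sample (n-1) standard deviation of percent swelling per solvent.
#' The sd is `NA` for a single replicate.
#'
#' @param dataset A `"swelling_dataset"`.
#' @param include_excluded Keep flagged solvents in the summary (default TRUE;
#'   the summary is descriptive, only estimation drops them).
#' @return Data frame with columns `solvent`, `n`, `mean`, `sd`, `excluded`.
#' @export
summarize_replicates <- function(dataset, include_excluded = TRUE) {
  stopifnot(inherits(dataset, "swelling_dataset"))
  obs <- dataset$observations
  if (!include_excluded) {
    obs <- obs[!obs$solvent %in% names(dataset$excluded), ]
  }
  if (nrow(obs) == 0L) stop("no observations to summarize", call. = FALSE)
  sp <- split(obs$percent_swelling, obs$solvent)
  # preserve first-appearance order rather than alphabetical
  sp <- sp[unique(obs$solvent)]
  out <- data.frame(
    solvent = names(sp),
    n = vapply(sp, length, integer(1)),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(v) if (length(v) > 1L) stats::sd(v) else NA_real_,
                numeric(1)),
    row.names = NULL
  )
  out$excluded <- out$solvent %in% names(dataset$excluded)
  out
}

#' Extract one repetition as per-solvent swelling values
#'
#' Convenience for the per-repetition estimation workflow: returns the
#' non-excluded solvents' percent swelling for a single replicate id as a
#' named vector.
#'
#' @param dataset A `"swelling_dataset"`.
#' @param replicate Replicate id to extract.
#' @return Named numeric vector (names are solvent names).
#' @export
repetition_swelling <- function(dataset, replicate) {
  stopifnot(inherits(dataset, "swelling_dataset"))
  obs <- dataset$observations
  obs <- obs[obs$replicate == replicate &
               !obs$solvent %in% names(dataset$excluded), ]
  if (nrow(obs) == 0L) {
    stop("no non-excluded observations for replicate ", replicate,
         call. = FALSE)
  }
  stats::setNames(obs$percent_swelling, obs$solvent)
}

# Display rounding: one decimal, half-up (so 5.65 -> 5.7, matching how
# swelling tables are conventionally printed). Full precision is kept
# internally; this is formatting only.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
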