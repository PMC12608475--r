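#' Read a component-level food HSP database
#'
#' One row per food component with its group label and HSP triple. Component
#' level is the granularity on which per-group mean Ra is computed the way the
#' screening method defines it (Ra per component, then averaged within group).
#'
#' @param path CSV with columns `name`, `group`, `delta_d`, `delta_p`,
#'   `delta_hb`.
#' @return Data frame of validated component records.
#' @export
read_components <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "group", "delta_d", "delta_p", "delta_hb")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("components file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("components file is empty", call. = FALSE)
  if (any(is.na(tab$group) | !nzchar(tab$group))) {
    stop("empty group label in row(s): ",
         paste(which(is.na(tab$group) | !nzchar(tab$group)), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("delta_d", "delta_p", "delta_hb")) {
    if (!is.numeric(tab[[col]])) {
      stop("non-numeric values in column ", col, call. = FALSE)
    }
  }
  for (i in seq_len(nrow(tab))) {
    validate_hsp(c(tab$delta_d[i], tab$delta_p[i], tab$delta_hb[i]),
                 what = paste0("component '", tab$name[i], "' (row ", i, ")"))
  }
  dup <- duplicated(tab[, c("group", "name")])
  if (any(dup)) {
    stop("duplicate component name(s) within a group: ",
         paste(unique(tab$name[dup]), collapse = ", "), call. = FALSE)
  }
  tab
}

#' Summarize a component database by group
#'
#' Per group: component count, component-wise mean HSP and sample (n-1)
#' standard deviation of each HSP component. Single-component groups get
#' sd 0 (or `NA` with `single_sd = "absent"`).
#'
#' @param components Data frame from [read_components()] (or of the same
#'   shape).
#' @param single_sd `"zero"` (default) or `"absent"` for n = 1 groups.
#' @return Data frame with columns `group`, `n`, `mean_d`, `sd_d`, `mean_p`,
#'   `sd_p`, `mean_hb`, `sd_hb` -- the same schema [read_group_summaries()]
#'   accepts.
#' @export
summarize_groups <- function(components, single_sd = c("zero", "absent")) {
  single_sd <- match.arg(single_sd)
  if (!is.data.frame(components) || nrow(components) == 0L) {
    stop("components must be a non-empty data frame", call. = FALSE)
  }
  groups <- unique(components$group)
  one <- function(g) {
    sub <- components[components$group == g, ]
    sdv <- function(v) {
      if (nrow(sub) > 1L) stats::sd(v)
      else if (single_sd == "zero") 0 else NA_real_
    }
    data.frame(group = g, n = nrow(sub),
               mean_d = mean(sub$delta_d), sd_d = sdv(sub$delta_d),
               mean_p = mean(sub$delta_p), sd_p = sdv(sub$delta_p),
               mean_hb = mean(sub$delta_hb), sd_hb = sdv(sub$delta_hb))
  }
  out <- do.call(rbind, lapply(groups, one))
  rownames(out) <- NULL
  out
}

#' Read group-level HSP summaries
#'
#' Group-level granularity: per-group mean and standard deviation of each HSP
#' component (and optionally the published per-group mean Ra to a reference
#' polymer, columns `mean_ra`/`sd_ra`, if available).
#'
#' @param path CSV with columns `group`, `n`, `mean_d`, `sd_d`, `mean_p`,
#'   `sd_p`, `mean_hb`, `sd_hb`.
#' @return Data frame of validated group summaries.
#' @export
read_group_summaries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "n", "mean_d", "sd_d", "mean_p", "sd_p",
            "mean_hb", "sd_hb")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("group summary file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("group summary file is empty", call. = FALSE)
  sds <- unlist(tab[, c("sd_d", "sd_p", "sd_hb")])
  if (any(sds < 0, na.rm = TRUE)) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (any(tab$n < 1, na.rm = TRUE)) {
    stop("group n must be >= 1", call. = FALSE)  # NA = count not published
  }
  for (i in seq_len(nrow(tab))) {
    validate_hsp(c(tab$mean_d[i], tab$mean_p[i], tab$mean_hb[i]),
                 what = paste0("group '", tab$group[i], "' mean"))
  }
  tab
}

#' Built-in food-component group summaries
#'
#' The shipped group-level database: mean and sd HSP of six food-component
#' groups (carbohydrates; fats and lipids; amino acids; vitamins; polar and
#' non-polar essential-oil components), summarizing 47 individual components,
#' plus the published per-group mean Ra to cross-linked cutin. Loaded from
#' the package's `extdata/food_group_summaries.csv`.
#'
#' @return Data frame in the [read_group_summaries()] schema with extra
#'   columns `mean_ra`, `sd_ra`.
#' @export
food_group_summaries <- function() {
  read_group_summaries(system.file("extdata", "food_group_summaries.csv",
                                   package = "hspcompat", mustWork = TRUE))
}

#' Construct a polymer record
#'
#' @param name Polymer name.
#' @param hsp HSP vector of the polymer.
#' @param ro An [ro_spec()] giving the interaction radius, or NULL if unknown
#'   (screening will then fail with a clear error naming the polymer).
#' @param source Citation or provenance text.
#' @return An object of class `"polymer_record"`.
#' @examples
#' polymer_record("cutin", hsp(19.7, 5.4, 2.5),
#'                ro_spec(reference_solvent = "hexane"))
#' @export
polymer_record <- function(name, hsp, ro = NULL, source = NA_character_) {
  if (!is.null(ro) && !inherits(ro, "ro_spec")) {
    stop("ro must be an ro_spec() or NULL", call. = FALSE)
  }
  structure(list(name = as.character(name), hsp = as_hsp(hsp), ro = ro,
                 source = source),
            class = "polymer_record")
}

#' @export
print.polymer_record <- function(x, ...) {
  v <- as.numeric(x$hsp)
  ro_txt <- if (is.null(x$ro)) "unspecified"
  else if (x$ro$mode == "numeric") sprintf("%g MPa^1/2", x$ro$value)
  else sprintf("Ra to %s", x$ro$reference_solvent)
  cat(sprintf("Polymer %s: HSP (%.1f, %.1f, %.1f), Ro %s\n",
              x$name, v[1], v[2], v[3], ro_txt))
  invisible(x)
}

#' Read polymer records from CSV
#'
#' Expected columns: `name`, `delta_d`, `delta_p`, `delta_hb`, `ro`,
#' `source`. The `ro` column holds either a number (MPa^(1/2)) or a solvent
#' name (Ro is then the Hansen distance from the polymer to that solvent);
#' empty means unknown. Rows with missing HSP values are kept as named
#' placeholders that error with a clear message when screened, so a database
#' can list a polymer whose parameters the user must supply.
#'
#' @param path CSV file path.
#' @return Named list of `"polymer_record"` objects (placeholders are
#'   entries of class `"polymer_placeholder"`).
#' @export
read_polymers <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(ro = "character"))
  need <- c("name", "delta_d", "delta_p", "delta_hb", "ro")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("polymers file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"source" %in% names(tab)) tab$source <- NA_character_
  out <- vector("list", nrow(tab))
  names(out) <- tab$name
  for (i in seq_len(nrow(tab))) {
    hsp_vals <- c(tab$delta_d[i], tab$delta_p[i], tab$delta_hb[i])
    if (anyNA(hsp_vals)) {
      out[[i]] <- structure(list(name = tab$name[i], source = tab$source[i]),
                            class = "polymer_placeholder")
      next
    }
    ro_raw <- tab$ro[i]
    ro <- if (is.na(ro_raw) || !nzchar(trimws(ro_raw))) {
      NULL
    } else if (!is.na(suppressWarnings(as.numeric(ro_raw)))) {
      ro_spec(value = as.numeric(ro_raw))
    } else {
      ro_spec(reference_solvent = trimws(ro_raw))
    }
    out[[i]] <- polymer_record(tab$name[i],
                               hsp(hsp_vals[1], hsp_vals[2], hsp_vals[3]),
                               ro = ro, source = tab$source[i])
  }
  out
}

#' @export
print.polymer_placeholder <- function(x, ...) {
  cat(sprintf("Polymer %s: placeholder, HSP must be supplied by the user\n",
              x$name))
  invisible(x)
}

#' Write a component database to CSV
#'
#' Inverse of [read_components()]; a write/read round-trip preserves values
#' to full double precision.
#'
#' @param components Component data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_components <- function(components, path) {
  out <- components[, c("name", "group", "delta_d", "delta_p", "delta_hb")]
  for (col in c("delta_d", "delta_p", "delta_hb")) {
    out[[col]] <- sprintf("%.17g", out[[col]])  # round-trips doubles exactly
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
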