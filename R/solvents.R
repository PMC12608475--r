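#' Built-in solvent HSP reference table
#'
#' Handbook Hansen parameters for the seven solvents of the default swelling
#' design (hexane, diethyl ether, chloroform, acetone, ethyl acetate,
#' isopropanol, water), spanning non-polar to strongly hydrogen-bonding.
#' Published handbook editions differ by a few tenths of MPa^(1/2) for some
#' solvents; supply your own table via [read_solvents()] to override.
#'
#' @return Data frame with columns `name`, `delta_d`, `delta_p`, `delta_hb`,
#'   `source`.
#' @export
hansen_solvents <- function() {
  data.frame(
    name = c("hexane", "diethyl ether", "chloroform", "acetone",
             "ethyl acetate", "isopropanol", "water"),
    delta_d = c(14.9, 14.5, 17.8, 15.5, 15.8, 15.8, 15.5),
    delta_p = c(0.0, 2.9, 3.1, 10.4, 5.3, 6.1, 16.0),
    delta_hb = c(0.0, 4.6, 5.7, 7.0, 7.2, 16.4, 42.3),
    source = "Hansen handbook values",
    stringsAsFactors = FALSE
  )
}

validate_solvent_table <- function(tab) {
  need <- c("name", "delta_d", "delta_p", "delta_hb")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("solvent table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("solvent table is empty", call. = FALSE)
  if (anyDuplicated(tab$name)) {
    stop("duplicate solvent name(s): ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    validate_hsp(c(tab$delta_d[i], tab$delta_p[i], tab$delta_hb[i]),
                 what = paste0("solvent '", tab$name[i], "'"))
  }
  invisible(tab)
}

#' Read a solvent HSP table from CSV
#'
#' Expected columns: `name`, `delta_d`, `delta_p`, `delta_hb`; `source` is
#' optional and kept if present.
#'
#' @param path Path to a CSV file with a header row.
#' @return Validated solvent table (data frame).
#' @export
read_solvents <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"source" %in% names(tab)) tab$source <- NA_character_
  tab$name <- as.character(tab$name)
  validate_solvent_table(tab)
  tab
}

# Look up one solvent's HSP from a table; error names the solvent.
solvent_hsp <- function(tab, name) {
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop("solvent '", name, "' not found in solvent table (have: ",
         paste(tab$name, collapse = ", "), ")", call. = FALSE)
  }
  hsp(tab$delta_d[i], tab$delta_p[i], tab$delta_hb[i])
}
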