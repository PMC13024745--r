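#' Load a group-contribution table for Hansen solubility parameters
#'
#' Reads (or returns the built-in) table of per-functional-group contributions
#' used by \code{\link{compute_hansen}}. Each row holds a group's dispersion
#' molar attraction constant `F_d` (MPa^0.5 cm^3/mol), polar constant `F_p`
#' (MPa^0.5 cm^3/mol), hydrogen-bond cohesion energy `E_h` (J/mol) and molar
#' volume increment `V` (cm^3/mol).
#'
#' The default table pairs Hoftyzer-van Krevelen `F_d`/`F_p`/`E_h` values with
#' Fedors molar-volume increments. Bare branch carbons (>CH-, >C<, =C<), whose
#' published volume increments are negative, are not listed as standalone rows;
#' instead the table ships composite groups with positive net volume: `CH_OH`
#' (carbinol methine, >CH- + OH), substituted benzene-ring composites, and
#' `ring_methylidene_cyclopentadiene` (an exocyclic =CH- plus three ring sp2
#' carbons plus ring closure, the indene-type 5-ring core). The sulfoxide row
#' `SO_sulfoxide` is backed out from the Hansen parameters of dimethyl
#' sulfoxide (delta_d 18.4, delta_p 16.4, delta_h 10.2 MPa^0.5 at 71.3
#' cm^3/mol) net of two CH3 groups.
#'
#' @param source `"default"` for the built-in table, or a path to a CSV file
#'   with columns `name,F_d,F_p,E_h,V`.
#' @return A data frame of class `hsp_group_table`.
#' @examples
#' tab <- load_group_table()
#' nrow(tab)
#' @export
load_group_table <- function(source = "default") {
  if (identical(source, "default")) {
    source <- system.file("extdata", "hvk_group_table.csv", package = "gelsolv")
  }
  if (!file.exists(source)) gs_stop("group table file not found: %s", source)
  tab <- utils::read.csv(source, stringsAsFactors = FALSE)
  required <- c("name", "F_d", "F_p", "E_h", "V")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    gs_stop("group table is missing column(s): %s",
            paste(missing_cols, collapse = ", "),
            class = "gelsolv_schema_error")
  }
  tab <- tab[required]
  if (nrow(tab) < 1L) gs_stop("group table has no rows")
  dup <- unique(tab$name[duplicated(tab$name)])
  if (length(dup)) {
    gs_stop("duplicated group name(s) in table: %s", paste(dup, collapse = ", "),
            class = "gelsolv_schema_error")
  }
  for (col in c("F_d", "F_p", "E_h", "V")) {
    if (!is.numeric(tab[[col]]) || anyNA(tab[[col]])) {
      gs_stop("column `%s` must be numeric with no missing values", col,
              class = "gelsolv_schema_error")
    }
  }
  bad_v <- which(tab$V <= 0)
  if (length(bad_v)) {
    gs_stop("non-positive molar volume V for group(s): %s",
            paste(tab$name[bad_v], collapse = ", "))
  }
  bad <- which(tab$F_d < 0 | tab$E_h < 0)
  if (length(bad)) {
    gs_stop("negative F_d or E_h for group(s): %s",
            paste(tab$name[bad], collapse = ", "))
  }
  structure(tab, class = c("hsp_group_table", "data.frame"),
            table_id = if (grepl("hvk_group_table", source)) "hvk-fedors-default" else source)
}

#' Read a molecule's functional-group composition from CSV
#'
#' @param file CSV with header `group,count`.
#' @param molecule_name Label for the molecule; defaults to the file name.
#' @return A named integer vector of group counts with attribute
#'   `molecule_name`.
#' @examples
#' sul <- read_composition(system.file("extdata", "sulindac_groups.csv",
#'                                     package = "gelsolv"))
#' @export
read_composition <- function(file, molecule_name = NULL) {
  if (!file.exists(file)) gs_stop("composition file not found: %s", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("group", "count") %in% names(df))) {
    gs_stop("composition file must have columns `group,count`: %s", file,
            class = "gelsolv_schema_error")
  }
  comp <- as_composition(stats::setNames(df$count, df$group))
  attr(comp, "molecule_name") <- molecule_name %||%
    sub("_groups\\.csv$", "", basename(file))
  comp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce named counts / data.frame to a validated composition vector
as_composition <- function(comp) {
  if (is.data.frame(comp)) comp <- stats::setNames(comp$count, comp$group)
  if (is.null(names(comp)) || any(!nzchar(names(comp)))) {
    gs_stop("composition must be a named vector of group counts")
  }
  if (!is.numeric(comp) || anyNA(comp) || any(comp < 0) ||
      any(comp != round(comp))) {
    gs_stop("group counts must be non-negative integers")
  }
  if (anyDuplicated(names(comp))) gs_stop("duplicated group names in composition")
  comp <- comp[comp > 0]
  if (length(comp) == 0L) gs_stop("composition must contain at least one group")
  comp
}

#' Group-contribution Hansen solubility parameters
#'
#' Computes the dispersion, polar and hydrogen-bonding Hansen components from
#' a functional-group decomposition, with each group weighted by its
#' occurrence count n_i and V_tot = sum(n_i V_i):
#' \deqn{\delta_d = \sum n_i F_{d,i} / V_{tot}}
#' \deqn{\delta_p = \sqrt{\sum n_i F_{p,i}^2} / V_{tot}}
#' \deqn{\delta_h = \sqrt{\sum n_i E_{h,i} / V_{tot}}}
#' and the total parameter \eqn{\delta^2 = \delta_d^2 + \delta_p^2 +
#' \delta_h^2}. With `E_h` in J/mol and `V` in cm^3/mol the result is in
#' MPa^0.5 (1 J/cm^3 = 1 MPa).
#'
#' @param composition Named vector of group counts (or a `group,count` data
#'   frame, or the result of [read_composition()]).
#' @param table A group table from [load_group_table()].
#' @return An object of class `hansen_parameters`: a list with `delta_d`,
#'   `delta_p`, `delta_h`, `delta_total` (MPa^0.5) and `molar_volume`
#'   (cm^3/mol).
#' @examples
#' meg <- read_composition(system.file("extdata", "meglumine_groups.csv",
#'                                     package = "gelsolv"))
#' compute_hansen(meg)
#' @export
compute_hansen <- function(composition, table = load_group_table()) {
  if (!inherits(table, "hsp_group_table")) table <- load_group_table(table)
  comp <- as_composition(composition)
  idx <- match(names(comp), table$name)
  if (anyNA(idx)) {
    gs_stop("unknown group name(s): %s",
            paste(names(comp)[is.na(idx)], collapse = ", "),
            class = "gelsolv_lookup_error")
  }
  n <- as.numeric(comp)
  v_tot <- sum(n * table$V[idx])
  if (v_tot <= 0) gs_stop("total molar volume must be positive")
  delta_d <- sum(n * table$F_d[idx]) / v_tot
  delta_p <- sqrt(sum(n * table$F_p[idx]^2)) / v_tot
  delta_h <- sqrt(sum(n * table$E_h[idx]) / v_tot)
  out <- list(
    molecule = attr(composition, "molecule_name") %||% NA_character_,
    delta_d = delta_d, delta_p = delta_p, delta_h = delta_h,
    delta_total = sqrt(delta_d^2 + delta_p^2 + delta_h^2),
    molar_volume = v_tot,
    table_id = attr(table, "table_id") %||% "user"
  )
  class(out) <- "hansen_parameters"
  out
}

#' @export
print.hansen_parameters <- function(x, ...) {
  cat("Hansen solubility parameters",
      if (!is.na(x$molecule)) sprintf("for %s", x$molecule) else "", "\n")
  cat(sprintf("  delta_d = %6.2f  delta_p = %6.2f  delta_h = %6.2f  MPa^0.5\n",
              x$delta_d, x$delta_p, x$delta_h))
  cat(sprintf("  delta_total = %.2f MPa^0.5   (V = %.1f cm^3/mol)\n",
              x$delta_total, x$molar_volume))
  invisible(x)
}

#' Screen a drug-ligand pair for miscibility by solubility-parameter difference
#'
#' Two components are predicted miscible when the absolute difference of their
#' total Hansen solubility parameters is below a threshold, conventionally
#' 7 MPa^0.5: below it the mixing interactions are considered sufficient to
#' overcome the demixing energy barrier.
#'
#' @param a,b Total solubility parameters (MPa^0.5), or `hansen_parameters`
#'   objects from [compute_hansen()].
#' @param threshold Miscibility cutoff in MPa^0.5 (default 7). The comparison
#'   is strict (`<`).
#' @return An object of class `miscibility_result` with fields `delta_a`,
#'   `delta_b`, `delta_diff`, `threshold` and `verdict` (`"miscible"` or
#'   `"immiscibility-risk"`).
#' @examples
#' miscibility_screen(23.74, 25.89)
#' @export
miscibility_screen <- function(a, b, threshold = 7.0) {
  da <- if (inherits(a, "hansen_parameters")) a$delta_total else a
  db <- if (inherits(b, "hansen_parameters")) b$delta_total else b
  gs_check_scalar(da, "a")
  gs_check_scalar(db, "b")
  gs_check_scalar(threshold, "threshold", min = 0)
  diff <- abs(da - db)
  out <- list(delta_a = da, delta_b = db, delta_diff = diff,
              threshold = threshold,
              verdict = if (diff < threshold) "miscible" else "immiscibility-risk")
  class(out) <- "miscibility_result"
  out
}

#' @export
print.miscibility_result <- function(x, ...) {
  cat(sprintf("Miscibility screen: |%.2f - %.2f| = %.2f MPa^0.5 (threshold %.1f)\n",
              x$delta_a, x$delta_b, x$delta_diff, x$threshold))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
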