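## Deterministic TSV report writers.

fmt_kcal <- function(x) sprintf("%+.2f", x)

#' Write an analysis report as TSV
#'
#' Reports mirror the conventional per-residue DTSS table layout: one row
#' per residue with its DTSS contribution (and, when available, the
#' crystal-conformation DTSS in parentheses), then footer rows for the
#' DTSS sum, the bare barrier `B0` and the estimate `B0 + sum(DTSS)`.
#' Writers are deterministic: identical inputs give byte-identical files.
#'
#' @param x a [barrier_estimate()] or [multiscan()] result.
#' @param path output path.
#' @param ... passed to methods.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, ...) UseMethod("write_report")

#' @rdname write_report
#' @export
write_report.barrier_estimate <- function(x, path, ...) {
  con <- file(path, "wb")
  on.exit(close(con))
  has_crystal <- "dtss_crystal" %in% names(x$contributions)
  writeLines("residue\tdtss_kcal_mol", con, sep = "\n")
  ct <- x$contributions
  for (i in seq_len(nrow(ct))) {
    val <- fmt_kcal(ct$dtss[i])
    if (has_crystal && is.finite(ct$dtss_crystal[i])) {
      val <- sprintf("%s (%s)", val, fmt_kcal(ct$dtss_crystal[i]))
    }
    writeLines(paste(ct$residue[i], val, sep = "\t"), con, sep = "\n")
  }
  writeLines(paste("sum_DTSS", fmt_kcal(x$sum_dtss), sep = "\t"), con, sep = "\n")
  writeLines(paste("B0", fmt_kcal(x$b0), sep = "\t"), con, sep = "\n")
  writeLines(paste("B0+sum_DTSS", fmt_kcal(x$total), sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' @rdname write_report
#' @param crystal optional [crystal_vs_scan_report()] tibble supplying the
#'   parenthesized crystal-conformation DTSS values.
#' @param b0 optional bare barrier (kcal/mol) to append the
#'   `B0 + sum(DTSS)` footer.
#' @export
write_report.multiscan_result <- function(x, path, crystal = NULL, b0 = NULL, ...) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("site\ttype\trotamer\tdtss_kcal_mol", con, sep = "\n")
  for (i in seq_len(nrow(x))) {
    val <- fmt_kcal(x$dtss[i])
    if (!is.null(crystal)) {
      j <- match(x$site_id[i], crystal$site_id)
      if (!is.na(j)) val <- sprintf("%s (%s)", val, fmt_kcal(crystal$dtss_crystal[j]))
    }
    writeLines(paste(x$site_id[i], x$type[i], x$rotamer_id[i], val, sep = "\t"),
               con, sep = "\n")
  }
  writeLines(paste("sum_DTSS", "", "", fmt_kcal(attr(x, "dtss_total")), sep = "\t"),
             con, sep = "\n")
  writeLines(paste("pair_term", "", "", fmt_kcal(attr(x, "pair_total")), sep = "\t"),
             con, sep = "\n")
  writeLines(paste("objective", "", "", fmt_kcal(attr(x, "objective")), sep = "\t"),
             con, sep = "\n")
  if (!is.null(b0)) {
    writeLines(paste("B0", "", "", fmt_kcal(b0), sep = "\t"), con, sep = "\n")
    writeLines(paste("B0+sum_DTSS", "", "",
                     fmt_kcal(b0 + attr(x, "dtss_total")), sep = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}

#' Write an alignment column report as TSV
#'
#' @param report a [conserved_charged_columns()] tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_column_report <- function(report, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("position\tresidues\tcharge_class\tconserved", con, sep = "\n")
  writeLines(paste(report$position, report$residues, report$charge_class,
                   ifelse(report$conserved, "yes", "no"), sep = "\t"),
             con, sep = "\n")
  invisible(path)
}
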