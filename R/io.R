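#' Read concentration-response profiles from long-format CSV
#'
#' Expects a comma-separated file with header columns
#' \code{substance_id}, \code{concentration_uM}, \code{response_pct} and
#' optionally \code{included}; one row per substance-concentration pair.
#' Rows are grouped by substance (in order of first appearance) and each
#' profile's concentrations sorted ascending; duplicate concentrations are
#' kept as distinct points.
#'
#' @param path Input file.
#' @return List of \code{\link{qhts_profile}} objects.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("substance_id", "concentration_uM", "response_pct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("concentration_uM", "response_pct"))
    if (!is.numeric(df[[col]]))
      stop(sprintf("column '%s' must be numeric", col))
  bad <- which(!is.finite(df$concentration_uM) | df$concentration_uM <= 0)
  if (length(bad))
    stop(sprintf("non-positive or missing concentration at data row %d",
                 bad[1]))
  bad <- which(!is.finite(df$response_pct))
  if (length(bad))
    stop(sprintf("missing response at data row %d", bad[1]))
  inc <- if ("included" %in% names(df)) as.logical(df$included)
         else rep(TRUE, nrow(df))
  ids <- unique(df$substance_id)
  lapply(ids, function(id) {
    sel <- df$substance_id == id
    qhts_profile(id, df$concentration_uM[sel], df$response_pct[sel],
                 inc[sel])
  })
}

#' Write activity-call records to CSV
#'
#' One row per substance with the call, stage, every stage-level p-value,
#' the fitted Hill parameters of both fits, \code{n_used} and
#' \code{outliers_removed}. Numeric columns are serialized with full
#' precision (\%.8g).
#'
#' @param records Data frame from \code{\link{classify_profiles}} (or
#'   rbind of \code{\link{classify}} rows).
#' @param path Output file.
#' @export
write_calls <- function(records, path) {
  cols <- c("substance_id", "call", "stage", "direction", "n_used",
            "outliers_removed", "p_f_nls", "p_f_wnls", "p_t_pos", "p_t_neg",
            "nls_r0", "nls_rmax", "nls_ac50", "nls_slope",
            "wnls_r0", "wnls_rmax", "wnls_ac50", "wnls_slope")
  cols <- intersect(cols, names(records))
  out <- records[, cols, drop = FALSE]
  for (col in names(out))
    if (is.numeric(out[[col]]) && !is.integer(out[[col]]))
      out[[col]] <- sprintf("%.8g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
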