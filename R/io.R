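#' Write analysis results to disk
#'
#' Scalar summaries are written as JSON, tables as CSV: an `nbd_ce` result
#' becomes a JSON object with keys `cost_tai`, `cost_sbc`, `qaly_tai`,
#' `qaly_sbc`, `delta_cost`, `delta_qaly`, `icer`, `icer_status`,
#' `perspective`, `fee_per_month`; tornado tables, PSA draws, CEAC tables,
#' utility curves, traces and any other data frame become CSV.  Costs in
#' JSON are reported rounded to whole yen; CSV round-trips reproduce values
#' to full double precision.
#'
#' @param x The result object.
#' @param path Destination file path.
#' @param ... Unused.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

#' @export
write_results.nbd_ce <- function(x, path, ...) {
  g <- glance(x)
  out <- list(cost_tai = round(g$cost_tai), cost_sbc = round(g$cost_sbc),
              qaly_tai = g$qaly_tai, qaly_sbc = g$qaly_sbc,
              delta_cost = round(g$delta_cost), delta_qaly = g$delta_qaly,
              icer = if (is.na(g$icer)) NULL else g$icer,
              icer_status = g$icer_status,
              perspective = g$perspective, fee_per_month = g$fee_per_month)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @export
write_results.data.frame <- function(x, path, ...) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Write per-arm cohort traces
#'
#' One CSV per arm with columns `cycle`, `age`, the six state occupancies,
#' `stoma_inflow`, `cost`, `qaly`, `disc_cost`, `disc_qaly`.
#'
#' @param ce An `nbd_ce` object.
#' @param dir Destination directory (created if missing).
#' @return The written paths, invisibly.
#' @export
write_traces <- function(ce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::imap_chr(ce$traces, function(tr, arm) {
    p <- file.path(dir, sprintf("trace_%s.csv", tolower(arm)))
    readr::write_csv(as_tibble(tr), p)
    p
  })
  invisible(paths)
}
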