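#' Published benchmark table values
#'
#' Returns the bundled copy of the printed per-classifier benchmark rows
#' (four experiments: single-backbone features, the second backbone, fused
#' features, and the selected subset), exactly as printed — including any
#' misprints, which [audit_metric_identities()] detects.
#'
#' @param tables Which experiment tables to return; default all.
#' @return Tibble with `table`, `classifier`, `recall`, `precision`, `f1`,
#'   `fnr`, `accuracy`, `time_sec` (all as printed; character columns for
#'   the metric cells so the printed precision is preserved).
#' @export
published_metrics <- function(tables = c(3L, 4L, 5L, 6L)) {
  path <- system.file("extdata", "published_metrics.csv",
                      package = "grainsight")
  df <- utils::read.csv(path, colClasses = c(
    table = "integer", classifier = "character", recall = "character",
    precision = "character", f1 = "character", fnr = "character",
    accuracy = "character", time_sec = "character"
  ))
  tibble::as_tibble(df[df$table %in% tables, , drop = FALSE])
}

printed_decimals <- function(s) {
  ifelse(grepl("\\.", s), nchar(sub("^[^.]*\\.", "", s)), 0L)
}

#' Audit the internal consistency of published metric rows
#'
#' Recomputes F1 (harmonic mean of the printed macro recall and precision)
#' and FNR (100 minus the printed recall) for every published row and
#' compares them with the printed cells at half a unit in the last printed
#' digit. Inconsistent cells are misprints in the source tables; the audit
#' reports them rather than papering over them.
#'
#' @param tables Which tables to audit; default 3:5 (the tables whose
#'   row-level identities are meant to hold; the selected-subset table has a
#'   grossly inconsistent first row and is excluded by default).
#' @return Tibble with one row per (table, classifier, metric): `printed`,
#'   `recomputed`, `tolerance`, `consistent`.
#' @export
audit_metric_identities <- function(tables = c(3L, 4L, 5L)) {
  pm <- published_metrics(tables)
  rows <- purrr::pmap(pm, function(table, classifier, recall, precision,
                                   f1, fnr, ...) {
    r <- as.numeric(recall); p <- as.numeric(precision)
    f1_hat <- 2 * r * p / (r + p)
    fnr_hat <- 100 - r
    tibble::tibble(
      table = table, classifier = classifier,
      metric = c("f1", "fnr"),
      printed = c(as.numeric(f1), as.numeric(fnr)),
      recomputed = c(f1_hat, fnr_hat),
      # half a unit in the last printed digit, plus a small epsilon for the
      # rounding already baked into the printed recall/precision inputs
      tolerance = 0.5 * 10^(-printed_decimals(c(f1, fnr))) + 1e-6
    )
  })
  out <- dplyr::bind_rows(rows)
  out$consistent <- abs(out$printed - out$recomputed) <= out$tolerance
  out
}
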