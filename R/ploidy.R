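## Flow-cytometry ploidy inference. Input is peak summaries (sample peak
## mean, internal-standard peak mean, CV%), not raw FCS histograms. The
## sample/standard fluorescence ratio times the standard's genome size
## gives relative 2C DNA content; ploidy is the nearest integer multiple
## of half a diploid reference 2C, within a tolerance.

#' Relative 2C DNA content from flow-cytometry peak means
#'
#' `(sample_peak / standard_peak) * standard_2c`. Linear in the sample
#' peak, inversely proportional to the standard peak, and invariant to
#' rescaling both peaks by the same factor.
#'
#' @param sample_peak,standard_peak positive fluorescence peak means
#'   (arbitrary units; vectorised).
#' @param standard_2c 2C genome size of the internal standard in pg
#'   (default 1, e.g. a rice standard of known unit genome size).
#' @return Relative 2C DNA content in pg.
#' @export
relative_2c <- function(sample_peak, standard_peak, standard_2c = 1) {
  if (any(sample_peak <= 0) || any(standard_peak <= 0) ||
      any(standard_2c <= 0))
    stop("peak means and standard 2C must be positive")
  (sample_peak / standard_peak) * standard_2c
}

#' Infer ploidy from relative 2C DNA content
#'
#' The continuous ploidy estimate is `p* = 2 * relative_2c /
#' diploid_ref_2c`; the call is the nearest integer when `|p* - round(p*)|
#' <= tolerance`, otherwise the record is flagged ambiguous rather than
#' silently assigned. The somatic chromosome number is `2n = ploidy *
#' base_x`.
#'
#' @param relative_2c relative 2C values in pg (vectorised).
#' @param diploid_ref_2c 2C of a confirmed diploid reference of the study
#'   group, in pg.
#' @param base_x base chromosome number (default 17, the Maloideae base
#'   number).
#' @param tolerance maximum deviation of `p*` from an integer (default
#'   0.25; wide enough for genome-size drift among tetraploids, narrow
#'   enough to reject midpoints).
#' @return Data frame: `relative_2c`, `p_star`, `ploidy` (`NA` when
#'   ambiguous), `two_n`, `ambiguous`.
#' @examples
#' infer_ploidy(2.38, diploid_ref_2c = 1.63)  # triploid, 2n = 51
#' @export
infer_ploidy <- function(relative_2c, diploid_ref_2c, base_x = 17L,
                         tolerance = 0.25) {
  if (diploid_ref_2c <= 0) stop("diploid_ref_2c must be positive")
  if (base_x < 1L) stop("base_x must be >= 1")
  p_star <- 2 * relative_2c / diploid_ref_2c
  p <- round(p_star)
  ambiguous <- abs(p_star - p) > tolerance | p < 1
  ploidy <- ifelse(ambiguous, NA_integer_, as.integer(p))
  data.frame(relative_2c = relative_2c, p_star = p_star, ploidy = ploidy,
             two_n = ploidy * as.integer(base_x), ambiguous = ambiguous)
}

#' Read a flow-cytometry peak-summary table
#'
#' CSV with columns `sample_id`, `sample_peak`, `standard_peak`,
#' `standard_2c`, `cv_percent`.
#'
#' @param path file path.
#' @return Data frame with a derived `relative_2c` column.
#' @export
read_fcm_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "sample_peak", "standard_peak", "standard_2c",
           "cv_percent")
  if (!all(req %in% names(x)))
    stop("FCM table must have columns ", paste(req, collapse = ", "))
  if (any(x$cv_percent < 0)) stop("cv_percent must be >= 0")
  x$relative_2c <- relative_2c(x$sample_peak, x$standard_peak,
                               x$standard_2c)
  x
}

#' Per-cytotype summary table
#'
#' Groups classified records by inferred ploidy and reports, per cytotype:
#' sample count, min-max and mean +/- SD of relative 2C, mean CV%, and the
#' somatic chromosome number. Ambiguous records are listed separately in
#' `attr(, "ambiguous")` and excluded from the summaries.
#'
#' @param records data frame with columns `relative_2c` and `cv_percent`
#'   (e.g. from [read_fcm_table()]).
#' @param diploid_ref_2c,base_x,tolerance passed to [infer_ploidy()].
#' @return Data frame, one row per cytotype, ordered by ploidy.
#' @export
cytotype_table <- function(records, diploid_ref_2c, base_x = 17L,
                           tolerance = 0.25) {
  if (!nrow(records)) stop("no records")
  if (is.null(records$relative_2c)) {
    if (is.null(records$sample_peak))
      stop("records need a relative_2c column or peak columns")
    records$relative_2c <- relative_2c(records$sample_peak,
                                       records$standard_peak,
                                       records$standard_2c)
  }
  inf <- infer_ploidy(records$relative_2c, diploid_ref_2c, base_x,
                      tolerance)
  records <- cbind(records, inf[, c("p_star", "ploidy", "two_n",
                                    "ambiguous")])
  ok <- records[!records$ambiguous, , drop = FALSE]
  amb <- records[records$ambiguous, , drop = FALSE]
  rows <- lapply(sort(unique(ok$ploidy)), function(p) {
    g <- ok[ok$ploidy == p, , drop = FALSE]
    data.frame(ploidy = p, two_n = p * as.integer(base_x), N = nrow(g),
               min_2c = min(g$relative_2c), max_2c = max(g$relative_2c),
               mean_2c = mean(g$relative_2c),
               sd_2c = if (nrow(g) > 1) stats::sd(g$relative_2c) else 0,
               mean_cv = mean(g$cv_percent))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ambiguous") <- amb
  out
}
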