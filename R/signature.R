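.signature_labels <- c(`1` = "Negatively Skewed", `2` = "Multi-Modal",
                       `3` = "Positively Skewed", `4` = "Bell-shaped")
.signature_codes <- c(NS = 1L, MM = 2L, PS = 3L, BS = 4L)

#' Histogram-based shape statistics of a carbon-density sample
#'
#' Computes the statistics driving the signature classification: the median
#' `Med` and its relative bin frequency `F_med`, the adjusted Fisher-Pearson
#' sample skewness `S_k` (computed on the raw values, not on bins), and --
#' after splitting the sample at the median into a left (`<= Med`) and right
#' (`> Med`) sub-sample -- the modal bin centers `M_L`, `M_R` and their
#' frequencies `F_ML`, `F_MR` plus the difference `D = F_MR - F_ML`.
#' All frequencies are relative to the *full* sample size, so sub-sample
#' mode frequencies are directly comparable to `F_med`. Ties between modal
#' bins are broken toward the bin nearer the median.
#'
#' @param sample Numeric vector of densities (n >= 30).
#' @param bin_width Histogram bin width in the sample's units (default 5,
#'   the Mg/ha convention; rescale it together with the data for other
#'   units).
#' @return A `signature_stats` list: `med`, `f_med`, `skewness`, `m_l`,
#'   `f_ml`, `m_r`, `f_mr`, `d`, `bin_width`, `n`, `degenerate`.
#' @export
distribution_stats <- function(sample, bin_width = 5) {
  sample <- sample[!is.na(sample)]
  if (length(sample) < 30) stop("sample size must be >= 30")
  if (bin_width <= 0) stop("bin_width must be > 0")
  n <- length(sample)
  degenerate <- (max(sample) - min(sample)) < .Machine$double.eps * max(1, abs(sample[1]))
  med <- stats::median(sample)
  if (degenerate) {
    return(structure(list(med = med, f_med = 1, skewness = NA_real_,
                          m_l = med, f_ml = 1, m_r = med, f_mr = 1, d = 0,
                          bin_width = bin_width, n = n, degenerate = TRUE),
                     class = "signature_stats"))
  }
  breaks <- seq(floor(min(sample) / bin_width) * bin_width,
                ceiling(max(sample) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(sample, breaks = breaks, plot = FALSE, right = FALSE)
  mids <- h$mids
  f <- h$counts / n
  f_med <- f[findInterval(med, breaks, rightmost.closed = TRUE)]
  sub_mode <- function(s) {
    if (length(s) == 0L) return(c(mode = med, freq = 0))
    hs <- graphics::hist(s, breaks = breaks, plot = FALSE, right = FALSE)
    fs <- hs$counts / n
    im <- which(fs == max(fs))
    im <- im[which.min(abs(mids[im] - med))]   # tie toward the median
    c(mode = mids[im], freq = fs[im])
  }
  left <- sub_mode(sample[sample <= med])
  right <- sub_mode(sample[sample > med])
  structure(list(med = med, f_med = f_med,
                 skewness = e1071::skewness(sample, type = 2),
                 m_l = left[["mode"]], f_ml = left[["freq"]],
                 m_r = right[["mode"]], f_mr = right[["freq"]],
                 d = right[["freq"]] - left[["freq"]],
                 bin_width = bin_width, n = n, degenerate = FALSE),
            class = "signature_stats")
}

#' @export
print.signature_stats <- function(x, ...) {
  cat(sprintf("<signature_stats> n=%d med=%.4g F_med=%.3f S_k=%.3f F_ML=%.3f F_MR=%.3f D=%.3f%s\n",
              x$n, x$med, x$f_med, x$skewness, x$f_ml, x$f_mr, x$d,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Classify a carbon-density distribution into its signature class
#'
#' Decision rule: multi-modal (MM) when both sub-sample modes are markedly
#' more frequent than the median bin (`F_ML >= tau_mm * F_med` and
#' `F_MR >= tau_mm * F_med`, two peaks flanking a median trough); otherwise
#' negatively skewed (NS) when `S_k <= -tau_s`, positively skewed (PS) when
#' `S_k >= tau_s`, bell-shaped (BS) for `|S_k| < tau_s`. Ties break toward
#' BS.
#'
#' @param stats A `signature_stats` from [distribution_stats()].
#' @param tau_s Skewness threshold (default 0.5, a conventional moderate
#'   skewness cut).
#' @param tau_mm Flank-mode prominence factor (default 1.2: both flank modes
#'   at least 20% more frequent than the median bin).
#' @return A `signature_class` list: `code` (1 = NS, 2 = MM, 3 = PS,
#'   4 = BS), `label`, `tag`.
#' @export
classify_signature <- function(stats, tau_s = 0.5, tau_mm = 1.2) {
  if (isTRUE(stats$degenerate)) stop("cannot classify a degenerate sample")
  tag <- if (stats$f_ml >= tau_mm * stats$f_med &&
             stats$f_mr >= tau_mm * stats$f_med) "MM"
         else if (stats$skewness <= -tau_s) "NS"
         else if (stats$skewness >= tau_s) "PS"
         else "BS"
  signature_class(tag)
}

#' Build a signature class from its tag or code
#'
#' @param x Tag (`"NS"`, `"MM"`, `"PS"`, `"BS"`) or integer code 1-4.
#' @return A `signature_class` list (`code`, `label`, `tag`).
#' @export
signature_class <- function(x) {
  if (is.character(x)) {
    if (!x %in% names(.signature_codes)) stop("unknown signature tag: ", x)
    code <- .signature_codes[[x]]
  } else {
    code <- as.integer(x)
    if (!code %in% 1:4) stop("signature code must be 1..4")
  }
  structure(list(code = code, label = .signature_labels[[as.character(code)]],
                 tag = names(.signature_codes)[code]),
            class = "signature_class")
}

#' @export
print.signature_class <- function(x, ...) {
  cat(sprintf("<signature_class> %d = %s (%s)\n", x$code, x$label, x$tag))
  invisible(x)
}

#' Tabulate signature classes into percentage shares
#'
#' @param classes Character vector of tags (or list of `signature_class`
#'   objects, or integer codes).
#' @param group Optional grouping vector (e.g. basin) of the same length.
#' @return Data frame with columns `group` (if given), `NS`, `MM`, `PS`,
#'   `BS` percentages summing to 100 within rounding per row, and `n`.
#' @export
signature_summary <- function(classes, group = NULL) {
  tags <- vapply(classes, function(x) {
    if (inherits(x, "signature_class")) x$tag
    else if (is.numeric(x)) signature_class(x)$tag
    else as.character(x)
  }, "")
  if (!all(tags %in% names(.signature_codes)))
    stop("unknown signature tag(s)")
  if (is.null(group)) group <- rep("all", length(tags))
  tab <- table(group, factor(tags, levels = names(.signature_codes)))
  pct <- 100 * prop.table(tab, 1)
  out <- data.frame(group = rownames(tab),
                    as.data.frame.matrix(pct), n = as.integer(rowSums(tab)),
                    row.names = NULL, check.names = FALSE)
  out
}

#' Write a sample's histogram as a two-column CSV
#'
#' Backs the per-ROI carbon-density histogram figures: bin center and
#' relative frequency.
#'
#' @param sample Numeric vector of densities.
#' @param path Output CSV path.
#' @param bin_width Histogram bin width (see [distribution_stats()]).
#' @return The path, invisibly.
#' @export
write_histogram_csv <- function(sample, path, bin_width = 5) {
  sample <- sample[!is.na(sample)]
  breaks <- seq(floor(min(sample) / bin_width) * bin_width,
                ceiling(max(sample) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(sample, breaks = breaks, plot = FALSE, right = FALSE)
  utils::write.csv(data.frame(bin_center = h$mids,
                              rel_freq = h$counts / length(sample)),
                   path, row.names = FALSE)
  invisible(path)
}
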