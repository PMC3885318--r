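# Scaling filters l(k) of the orthogonal Daubechies family, normalized so
# that sum(l) = sqrt(2). Standard published constants; db1 is the Haar pair.
.db_scaling <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079,
          0.2241438680420134, -0.12940952255126037),
  db3 = c(0.33267055295008263, 0.8068915093110925,
          0.45987750211849154, -0.13501102001025458,
          -0.08544127388202666, 0.03522629188570953),
  db4 = c(0.2303778133088965, 0.7148465705529157,
          0.6308807679298589, -0.027983769416859854,
          -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032)
)

#' Orthogonal wavelet filter bank
#'
#' Builds the analysis/synthesis filter quadruple for a named orthogonal
#' wavelet. The analysis low-pass is the scaling filter `l(k)` (summing to
#' `sqrt(2)`); the analysis high-pass is its quadrature-mirror counterpart
#' `h(k) = (-1)^k l(N-1-k)`; the synthesis filters are the time-reversed
#' analysis filters, as perfect reconstruction of an orthonormal bank
#' requires.
#'
#' @param name Wavelet identifier: `"haar"` (alias `"db1"`), `"db2"`,
#'   `"db3"` or `"db4"`. `"db3"` (6 taps, three vanishing moments) is the
#'   default mother wavelet of the fusion engine.
#' @return An object of class `filter_bank`: a list with elements `name`,
#'   `analysis_low`, `analysis_high`, `synthesis_low`, `synthesis_high`.
#' @examples
#' fb <- filter_bank("db3")
#' sum(fb$analysis_low)   # sqrt(2)
#' @export
filter_bank <- function(name = "db3") {
  key <- tolower(name)
  if (key == "haar") key <- "db1"
  l <- .db_scaling[[key]]
  if (is.null(l))
    stop(sprintf("unsupported wavelet '%s' (supported: haar, db1, db2, db3, db4)",
                 name), call. = FALSE)
  n <- length(l)
  h <- (-1)^(seq_len(n) - 1) * rev(l)
  structure(list(name = tolower(name),
                 analysis_low = l, analysis_high = h,
                 synthesis_low = rev(l), synthesis_high = rev(h)),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %s, %d taps\n", x$name, length(x$analysis_low)))
  invisible(x)
}

as_filter_bank <- function(bank) {
  if (inherits(bank, "filter_bank")) bank else filter_bank(bank)
}

#' Maximum dyadic decomposition depth
#'
#' The number of times the smaller image axis can be halved (with `ceil`
#' rounding) while a further split remains meaningful:
#' `floor(log2(min(height, width)))`. A 256 x 256 image therefore supports
#' 8 levels, the deepest scale of the multiscale fusion sweep.
#'
#' @param height,width Positive integer image dimensions.
#' @return Integer level capacity (0 for a 1 x 1 image).
#' @examples
#' max_decomposition_level(256, 256)  # 8
#' @export
max_decomposition_level <- function(height, width) {
  if (length(height) != 1L || length(width) != 1L ||
      !is.finite(height) || !is.finite(width) ||
      height < 1 || width < 1)
    stop("height and width must be positive integers", call. = FALSE)
  as.integer(floor(log2(min(height, width))))
}
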