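# Normalization of bias-corrected tracks and assembly of the HMM
# observation matrix. Pipeline order is fixed: bias-correct ->
# within-signal normalization -> (slope on the pre-logistic signal;
# logistic squashing for the norm channels).

#' Within-signal normalization
#'
#' Divides each value by the mean of the *non-zero* values inside its
#' enclosing bin; bins containing no non-zero value pass through unchanged.
#'
#' @param x Numeric track.
#' @param bin_size Bin width in bp (default 10000).
#' @return Normalized track, same length.
#' @export
within_normalize <- function(x, bin_size = 10000L) {
  stopifnot(bin_size >= 1L)
  bin <- (seq_along(x) - 1L) %/% bin_size
  for (b in unique(bin)) {
    idx <- which(bin == b)
    nz <- x[idx] != 0
    if (any(nz)) x[idx] <- x[idx] / mean(x[idx][nz])
  }
  x
}

#' Between-signal normalization
#'
#' Squashes a track into (0, 1) with the standard logistic
#' `f(v) = 1 / (1 + exp(-v))`, making channels from different fragment
#' classes comparable.
#'
#' @param x Numeric track (finite).
#' @return Track mapped into (0, 1).
#' @export
between_normalize <- function(x) {
  stopifnot(all(is.finite(x)))
  stats::plogis(x)
}

#' Savitzky-Golay slope of a track
#'
#' First derivative obtained by fitting a second-order polynomial in a
#' sliding window (Savitzky-Golay convolution).
#'
#' @param x Numeric track.
#' @param window Odd window length `>= 5` (default 9).
#' @param order Polynomial order (2).
#' @return Slope track, same length (exact for polynomials up to `order` at
#'   interior positions).
#' @export
savgol_slope <- function(x, window = 9L, order = 2L) {
  stopifnot(window %% 2L == 1L, window >= 5L)
  if (window > length(x)) stop("window larger than track")
  signal::sgolayfilt(x, p = order, n = window, m = 1L)
}

#' Signal decomposition strategy
#'
#' Declares which fragment-class signals enter the observation matrix and
#' whether strands are kept separate. Each (class, strand) pair contributes
#' a normalized-signal channel and a slope channel, so the dimension is
#' `2 * #classes * (1 + strand_specific)`, between 2 and 12.
#'
#' @param name One of `"All"`, `"Nfr"`, `"Nfr&+1N"`, `"Nfr&1N&+2N"`.
#' @param strand_specific Keep the two strands as separate channels?
#' @return An object of class `decomposition_strategy` with fields
#'   `classes`, `strand_specific` and the ordered `channels` data.frame.
#' @export
decomposition_strategy <- function(name = c("All", "Nfr", "Nfr&+1N",
                                            "Nfr&1N&+2N"),
                                   strand_specific = TRUE) {
  name <- match.arg(name)
  classes <- switch(name,
                    All = "All",
                    Nfr = "Nfr",
                    "Nfr&+1N" = c("Nfr", "+1N"),
                    "Nfr&1N&+2N" = c("Nfr", "1N", "+2N"))
  strands <- if (strand_specific) c("+", "-") else "*"
  channels <- expand.grid(feature = c("norm", "slope"), strand = strands,
                          class = classes, stringsAsFactors = FALSE)
  channels <- channels[, c("class", "strand", "feature")]
  structure(list(name = name, classes = classes,
                 strand_specific = strand_specific, channels = channels),
            class = "decomposition_strategy")
}

#' @export
print.decomposition_strategy <- function(x, ...) {
  cat(sprintf("<decomposition_strategy> %s, %s, %d channels\n", x$name,
              if (x$strand_specific) "strand-specific" else "strand-pooled",
              nrow(x$channels)))
  invisible(x)
}

#' Assemble the HMM observation matrix
#'
#' Takes bias-corrected tracks keyed by `"class/strand"` (e.g. `"Nfr/+"`,
#' or `"All/*"` for strand-pooled input) and produces the per-position
#' channel matrix: for every (class, strand) of the strategy, the
#' within-bin normalized and logistic-squashed signal, and the
#' Savitzky-Golay slope of the pre-logistic normalized signal.
#'
#' @param tracks Named list of numeric vectors (bias-corrected signals, all
#'   the same length) keyed `"class/strand"`.
#' @param strategy A [decomposition_strategy()].
#' @param bin_size Within-normalization bin size.
#' @param slope_window Savitzky-Golay window.
#' @return Numeric matrix, one row per position, `2 * #class * #strand`
#'   columns named `"class/strand/feature"`.
#' @export
assemble_observations <- function(tracks, strategy,
                                  bin_size = 10000L, slope_window = 9L) {
  keys <- unique(paste(strategy$channels$class, strategy$channels$strand,
                       sep = "/"))
  missing <- setdiff(keys, names(tracks))
  if (length(missing) > 0)
    stop("missing channel track(s): ", paste(missing, collapse = ", "))
  n <- unique(vapply(tracks[keys], length, integer(1)))
  stopifnot(length(n) == 1L)
  cols <- vector("list", nrow(strategy$channels))
  nms <- character(nrow(strategy$channels))
  for (i in seq_len(nrow(strategy$channels))) {
    ch <- strategy$channels[i, ]
    x <- tracks[[paste(ch$class, ch$strand, sep = "/")]]
    xn <- within_normalize(x, bin_size)
    cols[[i]] <- if (ch$feature == "norm") between_normalize(xn)
                 else savgol_slope(xn, slope_window)
    nms[i] <- paste(ch$class, ch$strand, ch$feature, sep = "/")
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nms
  m
}
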