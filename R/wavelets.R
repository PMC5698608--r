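# Orthogonal wavelet filter registry and the undecimated (MODWT) transform
# used by the baseline-suppression stage.

# Scaling (lowpass reconstruction) filter taps, sum = sqrt(2). sym8 is the
# least-asymmetric compactly supported orthogonal wavelet of order 8; its
# 16-tap support and smooth scaling function suit pulse-wave morphology.
.wavelet_registry <- list(
  sym8 = c(
    0.0018899503327594609, -0.0003029205147213668, -0.014952258337048231,
    0.0038087520138906151, 0.049137179673607506, -0.027219029917056003,
    -0.051945838107709037, 0.3644418948353314, 0.77718575170052351,
    0.48135965125837221, -0.061273359067658524, -0.14329423835080971,
    0.0076074873249176054, 0.031695087811492981, -0.00054213233179114812,
    -0.0033824159510061256
  )
)

#' Look up an orthogonal wavelet filter
#'
#' @param wavelet_id wavelet name; currently `"sym8"`.
#' @return list with `h` (scaling filter taps, sum `sqrt(2)`), `g` (wavelet
#'   filter by the quadrature-mirror relation) and `length` (tap count).
#' @export
wavelet_filter <- function(wavelet_id = "sym8") {
  if (!is.character(wavelet_id) || length(wavelet_id) != 1L ||
      !wavelet_id %in% names(.wavelet_registry)) {
    stop(sprintf(
      "unknown wavelet '%s' (available: %s)",
      as.character(wavelet_id)[1L], paste(names(.wavelet_registry), collapse = ", ")
    ), call. = FALSE)
  }
  h <- .wavelet_registry[[wavelet_id]]
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1L) * rev(h)  # quadrature mirror: g_l = (-1)^l h_{L-1-l}
  list(h = h, g = g, length = L)
}

#' Maximum useful decomposition level for a signal length
#'
#' The deepest level at which a wavelet with an `lw`-tap filter can still
#' resolve a signal of `n_samples` samples: `fix(log2(n_samples / (lw - 1)))`.
#' For a 1024-sample window and the 16-tap sym8 filter this gives 6 levels,
#' whose approximation band at 100 Hz covers roughly 0-0.8 Hz — the baseline
#' drift band.
#'
#' @param n_samples signal length in samples; must be at least
#'   `2 * filter_length`.
#' @param filter_length wavelet filter tap count (>= 2).
#' @return integer decomposition level (>= 1).
#' @examples
#' max_decomposition_level(1024, 16) # 6
#' @export
max_decomposition_level <- function(n_samples, filter_length) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || !is.finite(n_samples) ||
      n_samples != round(n_samples) || n_samples < 2) {
    stop("`n_samples` must be a single whole number >= 2", call. = FALSE)
  }
  if (!is.numeric(filter_length) || length(filter_length) != 1L ||
      !is.finite(filter_length) || filter_length != round(filter_length) ||
      filter_length < 2) {
    stop("`filter_length` must be a single whole number >= 2", call. = FALSE)
  }
  lev <- floor(log2(n_samples / (filter_length - 1)))
  if (n_samples < 2 * filter_length || lev < 1) {
    stop(sprintf(
      "no valid decomposition level for %d samples with a %d-tap filter",
      as.integer(n_samples), as.integer(filter_length)
    ), call. = FALSE)
  }
  as.integer(lev)
}

# --- MODWT core (circular; Percival & Walden scaling h/sqrt(2)) ------------

# y[t] = sum_l taps[l] * v[(t - step*(l-1)) mod N]   (analysis, looks back)
.circ_filter_back <- function(v, taps, step) {
  n <- length(v)
  y <- numeric(n)
  t0 <- seq_len(n) - 1L
  for (l in seq_along(taps)) {
    idx <- ((t0 - step * (l - 1L)) %% n) + 1L
    y <- y + taps[l] * v[idx]
  }
  y
}

# y[t] = sum_l taps[l] * v[(t + step*(l-1)) mod N]   (synthesis, looks forward)
.circ_filter_fwd <- function(v, taps, step) {
  n <- length(v)
  y <- numeric(n)
  t0 <- seq_len(n) - 1L
  for (l in seq_along(taps)) {
    idx <- ((t0 + step * (l - 1L)) %% n) + 1L
    y <- y + taps[l] * v[idx]
  }
  y
}

.modwt <- function(x, filt, level) {
  ht <- filt$h / sqrt(2)
  gt <- filt$g / sqrt(2)
  W <- vector("list", level)
  V <- x
  for (j in seq_len(level)) {
    step <- 2L^(j - 1L)
    W[[j]] <- .circ_filter_back(V, gt, step)
    V <- .circ_filter_back(V, ht, step)
  }
  list(W = W, V = V)
}

.imodwt <- function(W, V, filt) {
  ht <- filt$h / sqrt(2)
  gt <- filt$g / sqrt(2)
  for (j in rev(seq_along(W))) {
    step <- 2L^(j - 1L)
    V <- .circ_filter_fwd(V, ht, step) + .circ_filter_fwd(W[[j]], gt, step)
  }
  V
}

# Multiresolution detail at level j: inverse transform with all other bands
# zeroed. Zero-phase by construction (analysis + synthesis cancel the delay).
.modwt_mra_band <- function(coeffs, filt, j = NULL) {
  zero <- lapply(coeffs$W, function(w) numeric(length(w)))
  if (is.null(j)) {          # smooth (approximation)
    .imodwt(zero, coeffs$V, filt)
  } else {                   # detail j
    zero[[j]] <- coeffs$W[[j]]
    .imodwt(zero, numeric(length(coeffs$V)), filt)
  }
}
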