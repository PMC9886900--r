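#' Fixed-point encoding parameters for encrypted inference
#'
#' The inference protocol converts real-valued inputs and model weights to
#' integers by power-of-two scaling, and represents the (up to 44-bit) integer
#' results as residue pairs under two coprime plaintext moduli so that a
#' single BFV plaintext modulus does not limit precision.
#'
#' Defaults follow the protocol: inputs lie in `[0, 2^8)` and are scaled by
#' `2^s_x` with `s_x = 6` (14-bit scaled inputs), weights lie in `(-1, 1)` and
#' are scaled by `2^s_w` with `s_w = 14`, biases by `2^(s_x+s_w)`.  The
#' plaintext moduli are `t0 = 1,073,872,897` (30 usable bits) and
#' `t1 = 114,689` (16 bits), both primes congruent to 1 modulo `2n` so that
#' slot batching works at polynomial degree `n = 8192`.
#'
#' @param s_x input scale exponent (bits).
#' @param s_w weight scale exponent (bits).
#' @param t0,t1 coprime plaintext moduli (primes below `2^31`).
#' @param n polynomial degree (power of two, at least 8192 for 128-bit
#'   security in the encryption backend).
#' @param input_bits width of the raw input range: inputs must lie in
#'   `[0, 2^input_bits)`.
#' @return An object of class `"fp_params"`.
#' @examples
#' p <- fp_params()
#' required_output_bits(p, 40960)  # 44
#' @export
fp_params <- function(s_x = 6L, s_w = 14L,
                      t0 = 1073872897, t1 = 114689,
                      n = 8192L, input_bits = 8L) {
  s_x <- as.integer(s_x); s_w <- as.integer(s_w)
  n <- as.integer(n); input_bits <- as.integer(input_bits)
  stopifnot(s_x >= 0, s_w >= 0, input_bits >= 1, length(t0) == 1, length(t1) == 1)
  if (n < 2 || bitwAnd(n, n - 1L) != 0L)
    stop("polynomial degree n must be a power of two")
  t0 <- as.double(t0); t1 <- as.double(t1)
  if (t0 == t1) stop("plaintext moduli must be distinct")
  if (gcd_int(t0, t1) != 1) stop("plaintext moduli must be coprime")
  structure(
    list(s_x = s_x, s_w = s_w, t0 = t0, t1 = t1, n = n,
         input_bits = input_bits),
    class = "fp_params")
}

#' @export
print.fp_params <- function(x, ...) {
  cat("Fixed-point parameters for encrypted inference\n")
  cat(sprintf("  input scale  2^%d  (raw inputs in [0, 2^%d))\n", x$s_x, x$input_bits))
  cat(sprintf("  weight scale 2^%d, bias scale 2^%d\n", x$s_w, x$s_x + x$s_w))
  cat(sprintf("  plaintext moduli t0 = %.0f (%d bits), t1 = %.0f (%d bits)\n",
              x$t0, floor(log2(x$t0)), x$t1, floor(log2(x$t1))))
  cat(sprintf("  polynomial degree n = %d\n", x$n))
  invisible(x)
}

gcd_int <- function(a, b) {
  while (b != 0) { r <- a %% b; a <- b; b <- r }
  a
}

#' Output precision required by the fixed-point inference protocol
#'
#' A dot product over `f` features of `input_bits + s_x`-bit inputs and
#' `s_w`-bit weights needs `input_bits + s_x + s_w + ceiling(log2(f))` bits.
#' With the defaults and `f = 40960` this is 44 bits, which exceeds a single
#' BFV plaintext modulus and motivates the CRT residue pair.
#'
#' @param params an [fp_params()] object.
#' @param f number of features.
#' @return Integer number of bits.
#' @export
required_output_bits <- function(params, f) {
  stopifnot(inherits(params, "fp_params"))
  if (length(f) != 1 || is.na(f) || f < 1 || f != floor(f))
    stop("f must be a positive integer")
  as.integer(params$input_bits + params$s_x + params$s_w + ceiling(log2(f)))
}

# round to nearest, ties away from zero (R's round() is banker's rounding)
round_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Quantize inputs, weights and biases to protocol integers
#'
#' Inputs are scaled by `2^s_x`, weights by `2^s_w` and biases by
#' `2^(s_x+s_w)`; all are rounded to the nearest integer with ties away from
#' zero.  Inputs must be nonnegative and below `2^input_bits`; weights must
#' have magnitude strictly below 1 (rescale the model with
#' [normalize_model_weights()] if needed -- argmax inference is invariant to
#' a common positive rescaling of all rows of `W` and `b`).
#'
#' @param X numeric matrix (or vector) of raw inputs in `[0, 2^input_bits)`.
#' @param W numeric matrix of weights in `(-1, 1)`.
#' @param b numeric vector of biases.
#' @param params an [fp_params()] object.
#' @return Matrix/vector of integers (stored as doubles; values are exact).
#' @export
quantize_inputs <- function(X, params) {
  stopifnot(inherits(params, "fp_params"))
  lim <- 2^params$input_bits
  bad <- which(!is.finite(X) | X < 0 | X >= lim)
  if (length(bad) > 0)
    stop(sprintf("inputs outside [0, %d) at positions: %s", lim,
                 paste(utils::head(bad, 10), collapse = ", ")))
  q <- round_away(X * 2^params$s_x)
  # values at the very top of the range would round up to 2^(input_bits+s_x);
  # saturate at the largest code so scaled inputs always fit the stated width
  lim2 <- 2^(params$input_bits + params$s_x)
  q[q >= lim2] <- lim2 - 1
  q
}

#' @rdname quantize_inputs
#' @export
quantize_weights <- function(W, params) {
  stopifnot(inherits(params, "fp_params"))
  bad <- which(!is.finite(W) | abs(W) >= 1)
  if (length(bad) > 0)
    stop(sprintf("weights with |w| >= 1 at positions: %s",
                 paste(utils::head(bad, 10), collapse = ", ")))
  round_away(W * 2^params$s_w)
}

#' @rdname quantize_inputs
#' @export
quantize_bias <- function(b, params) {
  stopifnot(inherits(params, "fp_params"))
  if (any(!is.finite(b))) stop("biases must be finite")
  round_away(b * 2^(params$s_x + params$s_w))
}

#' Undo the fixed-point output scaling
#'
#' @param v integer-valued outputs of the fixed-point pipeline.
#' @param params an [fp_params()] object.
#' @return `v / 2^(s_x + s_w)`.
#' @export
descale <- function(v, params) {
  stopifnot(inherits(params, "fp_params"))
  v / 2^(params$s_x + params$s_w)
}

#' Split signed integers into CRT residue pairs and reconstruct them
#'
#' A signed integer `v` with `|v| < t0*t1/2` is represented by its residues
#' modulo `t0` and `t1` (negative values as `t - |v|`).  `crt_reconstruct()`
#' returns the centered representative in `(-t0*t1/2, t0*t1/2]`, so
#' `crt_reconstruct(crt_split(v))` is the identity on the legal range.
#'
#' @param v numeric vector/matrix of integers, `|v| < t0*t1/2`.
#' @param params an [fp_params()] object.
#' @return For `crt_split`, a list with elements `r0` and `r1` (same shape as
#'   `v`); for `crt_reconstruct`, signed integers.
#' @export
crt_split <- function(v, params) {
  stopifnot(inherits(params, "fp_params"))
  M <- params$t0 * params$t1
  if (any(!is.finite(v) | v != floor(v))) stop("values must be integers")
  if (any(abs(v) >= M / 2))
    stop("value magnitude exceeds t0*t1/2: CRT overflow")
  list(r0 = v %% params$t0, r1 = v %% params$t1)
}

#' @rdname crt_split
#' @param r0,r1 residues modulo `t0` and `t1`.
#' @export
crt_reconstruct <- function(r0, r1, params) {
  stopifnot(inherits(params, "fp_params"))
  t0 <- params$t0; t1 <- params$t1
  M <- t0 * t1
  # v = r0 + t0 * ((r1 - r0) * t0^{-1} mod t1); all intermediates < 2^48
  inv <- modinv(t0 %% t1, t1)
  k <- mulmod(((r1 - r0) %% t1 + t1) %% t1, inv, t1)
  v <- r0 + t0 * k
  out <- ifelse(v > M / 2, v - M, v)
  attributes(out) <- attributes(r0)
  out
}

# modular inverse via Fermat (m prime in all uses here)
modinv <- function(a, m) {
  r <- 1; b <- a %% m; e <- m - 2
  while (e > 0) {
    if (e %% 2 == 1) r <- mulmod(r, b, m)
    b <- mulmod(b, b, m)
    e <- e %/% 2
  }
  r
}

# vectorized (a * b) mod m for m < 2^31 without exceeding 2^53:
# split a into 15-bit halves
mulmod <- function(a, b, m) {
  a <- a %% m; b <- b %% m
  hi <- a %/% 32768
  lo <- a %% 32768
  (((hi * b) %% m) * 32768 + lo * b) %% m
}

#' Worst-case error of the fixed-point pipeline for one sample
#'
#' Bounds `|descale(fixed-point logits) - float logits|` per output:
#' quantizing inputs perturbs each entry by at most `2^(-s_x-1)`, weights by
#' `2^(-s_w-1)`, and the bias by `2^(-s_x-s_w-1)`.  If the gap between the two
#' largest float logits exceeds twice this bound, the fixed-point (and hence
#' encrypted) argmax matches the float argmax.
#'
#' @param x numeric vector of raw inputs (one sample).
#' @param W weight matrix, features x outputs.
#' @param params an [fp_params()] object.
#' @return Per-output numeric vector of error bounds.
#' @export
quantization_error_bound <- function(x, W, params) {
  stopifnot(inherits(params, "fp_params"))
  f <- length(x)
  stopifnot(nrow(W) == f)
  dx <- 2^(-params$s_x - 1)
  dw <- 2^(-params$s_w - 1)
  # |x_j| dw + |w_jk| dx + dx dw per feature, plus bias rounding
  colSums(abs(W)) * dx + sum(abs(x)) * dw + f * dx * dw +
    2^(-params$s_x - params$s_w - 1)
}

#' Bit-exact plaintext simulator of the packed encrypted matrix product
#'
#' Mirrors the encrypted circuit slot for slot, using length-`n` slot vectors
#' under each plaintext modulus in place of ciphertexts: the `ceiling(f/n)`
#' chunk pairs of each input row are multiplied slot-wise against the matching
#' weight chunks and summed; `log2(n)` rotate-and-add steps (a power-of-two
#' ladder over each slot half, then a half swap) leave the dot product in
#' every slot; a one-hot mask keeps the slot assigned to the (input, output)
#' pair, position `(i-1)*|Y| + (j-1)` taken modulo `n` in output ciphertext
#' `floor(((i-1)*|Y| + j-1)/n)`; masked results are compressed by addition.
#' Biases are added at the assigned slots.  Because every step is carried out
#' modulo `t0` and `t1` exactly as the homomorphic engine does, the decrypted
#' engine output must equal this simulation in every slot.
#'
#' @param X_q quantized input matrix (`|X|` x `f`, nonnegative integers).
#' @param W_q quantized weight matrix (`f` x `|Y|`, signed integers).
#' @param b_q quantized biases (length `|Y|`).
#' @param params an [fp_params()] object.
#' @param trace if `TRUE`, retain per-stage slot vectors for the first
#'   (input, output) pair (products, chunk sum, each ladder step, mask).
#' @return A list with `Z_q` (the `|X|` x `|Y|` signed integer result of
#'   `X_q %*% W_q + b_q` recovered from the slots), `slots` (per-modulus
#'   matrices of the compressed output ciphertext slots), `layout` (slot
#'   assignment table) and optionally `trace`.
#' @export
simulate_packed_matmul <- function(X_q, W_q, b_q, params, trace = FALSE) {
  stopifnot(inherits(params, "fp_params"))
  X_q <- as.matrix(X_q); W_q <- as.matrix(W_q)
  nX <- nrow(X_q); f <- ncol(X_q); nY <- ncol(W_q)
  stopifnot(nrow(W_q) == f, length(b_q) == nY)
  if (any(X_q != floor(X_q)) || any(W_q != floor(W_q)) || any(b_q != floor(b_q)))
    stop("simulate_packed_matmul expects quantized integer operands")
  if (any(X_q < 0)) stop("quantized inputs must be nonnegative")
  n <- params$n
  M <- params$t0 * params$t1
  bits <- required_output_bits(params, f)
  if (2^bits >= M)
    stop(sprintf(
      "required output precision (%d bits) overflows the CRT range (%.1f bits)",
      bits, log2(M)))
  chunks <- ceiling(f / n)
  tmods <- c(params$t0, params$t1)
  # residues and chunk packing per modulus
  pack_row <- function(v) {
    m <- matrix(0, chunks, n)
    idx <- seq_along(v)
    m[cbind((idx - 1) %/% n + 1, (idx - 1) %% n + 1)] <- v
    m
  }
  half <- n / 2
  rot_half <- function(v, r) {
    i <- c((r + 1):half, 1:r)
    c(v[i], v[half + i])
  }
  swap_halves <- function(v) c(v[(half + 1):n], v[1:half])
  n_out <- ceiling(nX * nY / n)
  slots <- lapply(tmods, function(t) matrix(0, n_out, n))
  tr <- if (trace) list() else NULL
  layout <- data.frame(i = integer(0), j = integer(0), ct = integer(0),
                       slot = integer(0))
  Wr <- lapply(tmods, function(t) (W_q %% t + t) %% t)
  Xr <- lapply(tmods, function(t) X_q %% t)
  for (i in seq_len(nX)) {
    xc <- lapply(seq_along(tmods), function(ti) pack_row(Xr[[ti]][i, ]))
    for (j in seq_len(nY)) {
      pos0 <- (i - 1) * nY + (j - 1)
      ct_i <- pos0 %/% n + 1
      slot_i <- pos0 %% n + 1
      layout <- rbind(layout, data.frame(i = i, j = j, ct = ct_i, slot = slot_i))
      for (ti in seq_along(tmods)) {
        t <- tmods[ti]
        wc <- pack_row(Wr[[ti]][, j])
        # column-wise products of each chunk pair, then chunk sum
        acc <- numeric(n)
        for (cc in seq_len(chunks)) {
          prod_c <- mulmod(xc[[ti]][cc, ], wc[cc, ], t)
          if (trace && i == 1 && j == 1) tr[[paste0("t", ti - 1, "_prod_chunk", cc)]] <- prod_c
          acc <- (acc + prod_c) %% t
        }
        if (trace && i == 1 && j == 1) tr[[paste0("t", ti - 1, "_chunk_sum")]] <- acc
        # log2(n) rotate-and-add: ladder over each half, then half swap
        r <- 1
        while (r <= half / 2) {
          acc <- (acc + rot_half(acc, r)) %% t
          if (trace && i == 1 && j == 1) tr[[paste0("t", ti - 1, "_ladder_", r)]] <- acc
          r <- r * 2
        }
        acc <- (acc + swap_halves(acc)) %% t
        if (trace && i == 1 && j == 1) tr[[paste0("t", ti - 1, "_ladder_cols")]] <- acc
        # one-hot mask at the assigned slot, additive compression
        slots[[ti]][ct_i, slot_i] <- (slots[[ti]][ct_i, slot_i] + acc[slot_i]) %% t
      }
    }
  }
  # bias at assigned slots
  for (ti in seq_along(tmods)) {
    t <- tmods[ti]
    br <- (b_q %% t + t) %% t
    for (r in seq_len(nrow(layout)))
      slots[[ti]][layout$ct[r], layout$slot[r]] <-
        (slots[[ti]][layout$ct[r], layout$slot[r]] + br[layout$j[r]]) %% t
  }
  Z_q <- matrix(0, nX, nY)
  picked <- cbind(layout$ct, layout$slot)
  Z_q[cbind(layout$i, layout$j)] <- crt_reconstruct(
    slots[[1]][picked], slots[[2]][picked], params)
  names(slots) <- c("t0", "t1")
  out <- list(Z_q = Z_q, slots = slots, layout = layout,
              n_output_ct = n_out, rotations_per_dot = as.integer(log2(n)))
  if (trace) out$trace <- tr
  out
}

#' Write a slot-level trace of the simulated circuit as compressed JSON
#'
#' @param sim result of [simulate_packed_matmul()] with `trace = TRUE`.
#' @param path output file; written gzip-compressed.
#' @return `path`, invisibly.
#' @export
write_matmul_trace <- function(sim, path) {
  if (is.null(sim$trace)) stop("simulation was run without trace = TRUE")
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(sim$trace, digits = NA), con)
  invisible(path)
}
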