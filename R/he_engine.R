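#' Create a BFV encryption context for private inference
#'
#' Builds the lattice context used by the encrypted pipeline: one polynomial
#' ring of degree `n` with an RNS ciphertext modulus sized for 128-bit
#' security (the homomorphic-encryption standard caps `log2(q)` at 218 bits
#' for `n = 8192`; the backend stays below it and refuses any degree for
#' which its modulus chain would be insecure), secret/public keys, and
#' Galois rotation keys for the power-of-two ladder plus the slot-half swap
#' -- exactly the `log2(n)` rotations one packed dot product needs.  The two
#' plaintext moduli `t0`, `t1` of `params` share the ring and keys; every
#' value travels as a ciphertext pair, one per modulus.
#'
#' The context is deterministic given `seed`.  Randomness comes from a
#' seeded splitmix64 stream, which makes experiments reproducible but is not
#' a cryptographically secure generator; treat this as a research
#' implementation of the scheme, not a hardened library.
#'
#' @param params an [fp_params()] object (supplies `n`, `t0`, `t1`).
#' @param seed integer seed for key generation and encryption randomness.
#' @return An object of class `"he_context"`.
#' @examples
#' \donttest{
#' ctx <- he_setup(fp_params(), seed = 1)
#' ctx
#' }
#' @export
he_setup <- function(params, seed = 1L) {
  stopifnot(inherits(params, "fp_params"))
  ptr <- .bfv_ctx_new(params$n, params$t0, params$t1, as.double(seed))
  structure(list(ptr = ptr, params = params, seed = as.integer(seed),
                 public_only = FALSE),
            class = "he_context")
}

#' @export
print.he_context <- function(x, ...) {
  info <- .bfv_ctx_info(x$ptr)
  cat("BFV context for private inference\n")
  cat(sprintf("  polynomial degree n = %d (%d slots), %d RNS primes, log2(q) = %.1f\n",
              info$n, info$n, info$k, info$log_q))
  cat(sprintf("  128-bit security bound on log2(q): %d bits\n", info$max_log_q_128))
  cat(sprintf("  plaintext moduli: %.0f, %.0f\n", info$t0, info$t1))
  cat(sprintf("  %s, %d Galois keys\n",
              if (info$has_secret_key) "secret key present" else "evaluation-only (no secret key)",
              info$n_galois_keys))
  invisible(x)
}

#' Export / import the public evaluation material of a context
#'
#' The server side of the protocol needs the public key and the Galois
#' rotation keys but must never see the secret key.  `he_public_blob()`
#' serializes exactly that material; `he_evaluation_context()` rebuilds an
#' evaluation-only context from it.  Decryption with such a context fails.
#'
#' @param ctx an [he_setup()] context.
#' @param blob a raw vector from `he_public_blob()`.
#' @param params the matching [fp_params()].
#' @return A raw vector, or an evaluation-only `"he_context"`.
#' @export
he_public_blob <- function(ctx) {
  stopifnot(inherits(ctx, "he_context"))
  .bfv_public_blob(ctx$ptr)
}

#' @rdname he_public_blob
#' @export
he_evaluation_context <- function(blob, params) {
  stopifnot(is.raw(blob), inherits(params, "fp_params"))
  ptr <- .bfv_ctx_from_blob(blob)
  info <- .bfv_ctx_info(ptr)
  if (info$t0 != params$t0 || info$t1 != params$t1 || info$n != params$n)
    stop("public material does not match these fixed-point parameters")
  structure(list(ptr = ptr, params = params, seed = NA_integer_,
                 public_only = TRUE),
            class = "he_context")
}

# slot chunking shared by client and server: row-major, zero-padded
chunk_indices <- function(f, n) {
  chunks <- ceiling(f / n)
  lapply(seq_len(chunks), function(cc) {
    lo <- (cc - 1) * n + 1
    hi <- min(cc * n, f)
    lo:hi
  })
}

#' Encrypt a quantized input matrix for the packed inference protocol
#'
#' Packs `n` features of each input row into one plaintext polynomial, so a
#' row becomes `ceiling(f/n)` ciphertext pairs (one ciphertext per plaintext
#' modulus).  With the protocol defaults, 40,960 features fit in 5
#' ciphertext chunks.  Trailing slots of the last chunk are zero-padded.
#'
#' @param X_q quantized input matrix (`|X|` x `f`, nonnegative integers, see
#'   [quantize_inputs()]).
#' @param ctx an [he_setup()] context.
#' @return An object of class `"packed_cipher_matrix"`.
#' @export
he_encrypt_inputs <- function(X_q, ctx) {
  stopifnot(inherits(ctx, "he_context"))
  X_q <- as.matrix(X_q)
  if (any(X_q < 0) || any(X_q != floor(X_q)))
    stop("inputs must be quantized nonnegative integers")
  p <- ctx$params
  if (max(X_q) >= min(p$t0, p$t1))
    stop("quantized input exceeds a plaintext modulus; check the scale parameters")
  f <- ncol(X_q)
  n <- p$n
  idx <- chunk_indices(f, n)
  ct <- lapply(seq_len(nrow(X_q)), function(i) {
    lapply(idx, function(ii) {
      v <- numeric(n)
      v[seq_along(ii)] <- X_q[i, ii]
      list(.bfv_encrypt(ctx$ptr, v, 0L), .bfv_encrypt(ctx$ptr, v, 1L))
    })
  })
  structure(list(ct = ct, n_rows = nrow(X_q), f = f, chunks = length(idx),
                 public = list(n = n, t0 = p$t0, t1 = p$t1, s_x = p$s_x)),
            class = "packed_cipher_matrix")
}

#' @export
print.packed_cipher_matrix <- function(x, ...) {
  cat(sprintf("Encrypted input matrix: %d rows x %d features in %d ciphertext chunk(s)/row\n",
              x$n_rows, x$f, x$chunks))
  cat(sprintf("  transmitted public values: n = %d, T = {%.0f, %.0f}, s_x = %d\n",
              x$public$n, x$public$t0, x$public$t1, x$public$s_x))
  invisible(x)
}

#' Encode the model for server-side encrypted evaluation
#'
#' The server encodes the transpose of the quantized weight matrix: the
#' weights of output `j` are packed along slots into `ceiling(f/n)` plaintext
#' polynomials (an `|Y|` x `ceiling(f/n)` grid), matching the packing of the
#' encrypted inputs.  Each bias is encoded as a polynomial with all slots
#' equal to its value.  Weights may be negative; residues are taken modulo
#' each plaintext modulus and centre-lifted inside the backend.
#'
#' @param W_q quantized weight matrix (`f` x `|Y|`, see [quantize_weights()]).
#' @param b_q quantized biases (length `|Y|`, see [quantize_bias()]).
#' @param ctx an [he_setup()] or [he_evaluation_context()] context.
#' @return An object of class `"encoded_model"`.
#' @export
he_encode_weights <- function(W_q, b_q, ctx) {
  stopifnot(inherits(ctx, "he_context"))
  W_q <- as.matrix(W_q)
  nY <- ncol(W_q)
  if (length(b_q) != nY) stop("bias length must match the number of outputs")
  if (any(W_q != floor(W_q)) || any(b_q != floor(b_q)))
    stop("model must be quantized to integers first")
  p <- ctx$params
  n <- p$n
  f <- nrow(W_q)
  idx <- chunk_indices(f, n)
  tmods <- c(p$t0, p$t1)
  pt <- lapply(seq_len(nY), function(j) {
    lapply(idx, function(ii) {
      w <- W_q[ii, j]
      lapply(1:2, function(ti) {
        t <- tmods[ti]
        v <- numeric(n)
        v[seq_along(w)] <- (w %% t + t) %% t
        .bfv_encode_plain(ctx$ptr, v, ti - 1L)
      })
    })
  })
  bias_allslots <- lapply(seq_len(nY), function(j) {
    lapply(1:2, function(ti) {
      t <- tmods[ti]
      rep((b_q[j] %% t + t) %% t, n)
    })
  })
  structure(list(pt = pt, b_q = b_q, bias_allslots = bias_allslots,
                 f = f, n_outputs = nY, chunks = length(idx)),
            class = "encoded_model")
}

#' Packed encrypted matrix multiplication
#'
#' The core circuit: for every (input row, output) pair it multiplies the
#' encrypted input chunks slot-wise by the matching encoded weight chunks,
#' adds the chunk products together, runs `log2(n)` rotate-and-add steps so
#' that every slot holds the dot product, masks the slot assigned to the
#' pair (position `(i-1)*|Y| + (j-1) mod n`, row-major over inputs then
#' outputs), and compresses all masked results by addition, appending a new
#' output ciphertext whenever `|X| * |Y|` exceeds the slot count `n`.  The
#' work per pair is independent, so any execution order gives identical
#' results; this implementation is single-threaded.
#'
#' @param Xhat a [he_encrypt_inputs()] matrix.
#' @param model a [he_encode_weights()] encoded model.
#' @param ctx the evaluation context.
#' @return An object of class `"encrypted_result"` whose ciphertexts hold
#'   the dot products (without biases; see [he_add_bias()]).
#' @export
he_matmul <- function(Xhat, model, ctx) {
  stopifnot(inherits(Xhat, "packed_cipher_matrix"),
            inherits(model, "encoded_model"),
            inherits(ctx, "he_context"))
  if (Xhat$chunks != model$chunks || Xhat$f != model$f)
    stop("encrypted inputs and encoded model disagree on the feature layout")
  n <- ctx$params$n
  logn <- as.integer(log2(n))
  nX <- Xhat$n_rows
  nY <- model$n_outputs
  n_out <- ceiling(nX * nY / n)
  out <- vector("list", n_out)
  rotations <- 0L
  for (i in seq_len(nX)) {
    for (j in seq_len(nY)) {
      pos0 <- (i - 1) * nY + (j - 1)
      ct_i <- pos0 %/% n + 1
      slot_i <- pos0 %% n + 1
      mask <- numeric(n)
      mask[slot_i] <- 1
      pair <- vector("list", 2)
      for (ti in 1:2) {
        acc <- NULL
        for (cc in seq_len(Xhat$chunks)) {
          prod_c <- .bfv_mul_plain(ctx$ptr, Xhat$ct[[i]][[cc]][[ti]],
                                   model$pt[[j]][[cc]][[ti]])
          acc <- if (is.null(acc)) prod_c else .bfv_add_ct(ctx$ptr, acc, prod_c)
        }
        r <- 1L
        while (r <= n / 4) {
          acc <- .bfv_add_ct(ctx$ptr, acc, .bfv_rotate_rows(ctx$ptr, acc, r))
          rotations <- rotations + 1L
          r <- r * 2L
        }
        acc <- .bfv_add_ct(ctx$ptr, acc, .bfv_rotate_cols(ctx$ptr, acc))
        rotations <- rotations + 1L
        masked <- .bfv_mul_plain(ctx$ptr,
                                 acc, .bfv_encode_plain(ctx$ptr, mask, ti - 1L))
        pair[[ti]] <- masked
      }
      if (is.null(out[[ct_i]])) {
        out[[ct_i]] <- pair
      } else {
        out[[ct_i]] <- list(.bfv_add_ct(ctx$ptr, out[[ct_i]][[1]], pair[[1]]),
                            .bfv_add_ct(ctx$ptr, out[[ct_i]][[2]], pair[[2]]))
      }
    }
  }
  structure(list(ct = out, n_rows = nX, n_outputs = nY, n_output_ct = n_out,
                 bias_added = FALSE,
                 rotations_per_dot = logn,
                 total_rotations = rotations),
            class = "encrypted_result")
}

#' Add encoded biases to an encrypted result
#'
#' Adds bias `b_j` at every slot assigned to output `j` in the compressed
#' layout, completing `Y = X W + b`.  Adding biases twice is rejected.
#'
#' @param Yhat an [he_matmul()] result.
#' @param model the [he_encode_weights()] encoded model (source of biases).
#' @param ctx the evaluation context.
#' @return The updated `"encrypted_result"`.
#' @export
he_add_bias <- function(Yhat, model, ctx) {
  stopifnot(inherits(Yhat, "encrypted_result"),
            inherits(model, "encoded_model"),
            inherits(ctx, "he_context"))
  if (Yhat$bias_added) stop("biases were already added to this result")
  if (model$n_outputs != Yhat$n_outputs)
    stop("encoded model does not match the layout of this result")
  n <- ctx$params$n
  tmods <- c(ctx$params$t0, ctx$params$t1)
  nY <- Yhat$n_outputs
  for (ct_i in seq_len(Yhat$n_output_ct)) {
    pos0 <- (ct_i - 1) * n + seq_len(n) - 1      # global positions in this ct
    live <- pos0 < Yhat$n_rows * nY
    jidx <- pos0 %% nY + 1                        # output index per slot
    for (ti in 1:2) {
      t <- tmods[ti]
      v <- numeric(n)
      v[live] <- ((model$b_q[jidx[live]] %% t) + t) %% t
      Yhat$ct[[ct_i]][[ti]] <- .bfv_add_plain(ctx$ptr, Yhat$ct[[ct_i]][[ti]],
                                              v, ti - 1L)
    }
  }
  Yhat$bias_added <- TRUE
  Yhat
}

#' Decrypt, decode and descale an encrypted inference result
#'
#' The client decrypts each output ciphertext pair, reads the slots of both
#' residues, reconstructs signed integers through the CRT, regroups them by
#' (input, output) position and descales by `2^(s_x+s_w)`.  The predicted
#' class of each input row is the argmax of its outputs (ties broken towards
#' the lowest class index).  Decryption refuses to return values once the
#' noise budget is exhausted, since the slots would be corrupt.
#'
#' @param Yhat an [he_matmul()] (+ [he_add_bias()]) result.
#' @param ctx the client context holding the secret key.
#' @return A list with `Z` (descaled real outputs, `|X|` x `|Y|`), `Z_q`
#'   (raw integers), `classes` (0-based argmax per row) and
#'   `noise_budget` (bits remaining, minimum over ciphertexts).
#' @export
he_decrypt_decode <- function(Yhat, ctx) {
  stopifnot(inherits(Yhat, "encrypted_result"), inherits(ctx, "he_context"))
  if (ctx$public_only) stop("this context holds no secret key")
  n <- ctx$params$n
  nX <- Yhat$n_rows
  nY <- Yhat$n_outputs
  budget <- Inf
  slots <- lapply(1:2, function(ti) matrix(0, Yhat$n_output_ct, n))
  for (ct_i in seq_len(Yhat$n_output_ct)) {
    for (ti in 1:2) {
      d <- .bfv_decrypt(ctx$ptr, Yhat$ct[[ct_i]][[ti]], ti - 1L)
      budget <- min(budget, attr(d, "noise_budget"))
      slots[[ti]][ct_i, ] <- as.numeric(d)
    }
  }
  if (budget <= 0)
    stop("noise budget exhausted: decrypted values would be corrupt")
  pos0 <- seq_len(nX * nY) - 1
  ct_i <- pos0 %/% n + 1
  slot_i <- pos0 %% n + 1
  Z_q <- matrix(crt_reconstruct(slots[[1]][cbind(ct_i, slot_i)],
                                slots[[2]][cbind(ct_i, slot_i)],
                                ctx$params),
                nX, nY, byrow = TRUE)
  Z <- descale(Z_q, ctx$params)
  classes <- max.col(Z, ties.method = "first") - 1L
  list(Z = Z, Z_q = Z_q, classes = classes, noise_budget = budget,
       slots = setNames(slots, c("t0", "t1")))
}

#' End-to-end encrypted inference for a quantized model
#'
#' Convenience wrapper running the full client/server round trip in-process:
#' encrypt inputs, evaluate `X W + b` under encryption, add biases, decrypt
#' and take the argmax.
#'
#' @param X raw input matrix (real values in `[0, 2^input_bits)`).
#' @param W weight matrix (`f` x `|Y|`, magnitudes below 1).
#' @param b bias vector.
#' @param ctx an [he_setup()] context.
#' @return As [he_decrypt_decode()].
#' @export
he_infer <- function(X, W, b, ctx) {
  p <- ctx$params
  X_q <- quantize_inputs(X, p)
  W_q <- quantize_weights(W, p)
  b_q <- quantize_bias(b, p)
  Xhat <- he_encrypt_inputs(X_q, ctx)
  enc <- he_encode_weights(W_q, b_q, ctx)
  Yhat <- he_add_bias(he_matmul(Xhat, enc, ctx), enc, ctx)
  he_decrypt_decode(Yhat, ctx)
}

#' Timing harness for the packed and naive encrypted matrix products
#'
#' Measures wall-clock time per phase (encrypt, compute, decrypt) of the
#' packed algorithm for each requested batch size, optionally alongside a
#' naive baseline that packs samples (not features) along slots: the naive
#' layout computes each output as `f` ciphertext-plaintext multiplications
#' and additions, so its cost is roughly flat in the number of samples until
#' the slot count is exceeded, whereas the packed path grows linearly with
#' the batch.  Numbers are reported, never asserted.
#'
#' @param ctx an [he_setup()] context.
#' @param batch_sizes integer vector of batch sizes `|X|` to time.
#' @param f number of features.
#' @param n_outputs number of model outputs.
#' @param naive include the naive standard-matmul baseline.
#' @param seed seed for the random instance.
#' @return A data frame with one row per (method, batch size).
#' @export
he_benchmark <- function(ctx, batch_sizes = c(1L, 2L, 4L), f = 256L,
                         n_outputs = 3L, naive = TRUE, seed = 1L) {
  stopifnot(inherits(ctx, "he_context"))
  p <- ctx$params
  rows <- list()
  for (bs in batch_sizes) {
    inst <- generate_random_inference_instance(bs, f, n_outputs, seed)
    X_q <- quantize_inputs(inst$X, p)
    W_q <- quantize_weights(inst$W, p)
    b_q <- quantize_bias(inst$b, p)
    t_enc <- unname(system.time(Xhat <- he_encrypt_inputs(X_q, ctx))[3])
    enc <- he_encode_weights(W_q, b_q, ctx)
    t_cmp <- unname(system.time(Yhat <- he_add_bias(he_matmul(Xhat, enc, ctx), enc, ctx))[3])
    t_dec <- unname(system.time(he_decrypt_decode(Yhat, ctx))[3])
    rows[[length(rows) + 1]] <- data.frame(
      method = "packed", batch = bs, f = f,
      encrypt_s = t_enc, compute_s = t_cmp, decrypt_s = t_dec)
    if (naive) {
      tn <- naive_he_lr_time(ctx, X_q, W_q, b_q)
      rows[[length(rows) + 1]] <- data.frame(
        method = "naive", batch = bs, f = f,
        encrypt_s = tn["encrypt"], compute_s = tn["compute"],
        decrypt_s = tn["decrypt"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# standard HE logistic-regression layout: one ciphertext per feature column,
# samples along slots; outputs need f ct*pt multiplications each
naive_he_lr_time <- function(ctx, X_q, W_q, b_q) {
  p <- ctx$params
  n <- p$n
  nX <- nrow(X_q); f <- ncol(X_q); nY <- ncol(W_q)
  if (nX > n) stop("naive baseline supports at most n samples per ciphertext")
  t_enc <- system.time({
    cols <- lapply(seq_len(f), function(jf) {
      v <- numeric(n)
      v[seq_len(nX)] <- X_q[, jf]
      list(.bfv_encrypt(ctx$ptr, v, 0L), .bfv_encrypt(ctx$ptr, v, 1L))
    })
  })[3]
  tmods <- c(p$t0, p$t1)
  t_cmp <- system.time({
    outs <- lapply(seq_len(nY), function(j) {
      lapply(1:2, function(ti) {
        t <- tmods[ti]
        acc <- NULL
        for (jf in seq_len(f)) {
          wv <- rep(((W_q[jf, j] %% t) + t) %% t, n)
          pr <- .bfv_mul_plain(ctx$ptr, cols[[jf]][[ti]],
                               .bfv_encode_plain(ctx$ptr, wv, ti - 1L))
          acc <- if (is.null(acc)) pr else .bfv_add_ct(ctx$ptr, acc, pr)
        }
        .bfv_add_plain(ctx$ptr, acc, rep(((b_q[j] %% t) + t) %% t, n), ti - 1L)
      })
    })
  })[3]
  t_dec <- system.time({
    for (j in seq_len(nY))
      for (ti in 1:2) .bfv_decrypt(ctx$ptr, outs[[j]][[ti]], ti - 1L)
  })[3]
  c(encrypt = unname(t_enc), compute = unname(t_cmp), decrypt = unname(t_dec))
}
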