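# The shared context (helper-oracles.R) is created once per run: key
# generation is deterministic given the seed, and the 128-bit security
# check runs inside setup.

test_that("insecure or malformed encryption parameters are rejected at setup", {
  expect_error(fp_params(n = 12345), "power of two")
  # degrees whose modulus chain cannot reach 128-bit security are refused
  expect_error(he_setup(fp_params(n = 1024), seed = 1), "security")
  expect_error(he_setup(fp_params(n = 4096), seed = 1), "security")
  # a plaintext modulus without batching support for the ring is refused
  expect_error(he_setup(fp_params(t0 = 1073872897, t1 = 114687), seed = 1))
})

test_that("fresh encrypt-decrypt is the identity and reports a healthy noise budget", {
  ctx <- shared_he_ctx()
  n <- ctx$params$n
  set.seed(2)
  v <- floor(runif(n, 0, ctx$params$t1))
  for (ti in 0:1) {
    ct <- helr:::.bfv_encrypt(ctx$ptr, v, ti)
    d <- helr:::.bfv_decrypt(ctx$ptr, ct, ti)
    expect_identical(as.numeric(d), as.numeric(v))
    expect_gt(attr(d, "noise_budget"), 100)
  }
})

test_that("input packing yields ceiling(f/n) ciphertext chunks per row", {
  ctx <- shared_he_ctx()
  n <- ctx$params$n
  # the protocol's headline case: 40,960 features -> 5 ciphertexts
  X40k <- matrix(seq_len(40960) %% 256, 1, 40960)
  Xhat <- he_encrypt_inputs(X40k, ctx)
  expect_equal(Xhat$chunks, 5L)
  # f = n -> a single chunk, recovered exactly on decryption
  Xn <- matrix(floor(runif(n, 0, 2^14)), 1, n)
  Xhat1 <- he_encrypt_inputs(Xn, ctx)
  expect_equal(Xhat1$chunks, 1L)
  d <- helr:::.bfv_decrypt(ctx$ptr, Xhat1$ct[[1]][[1]][[1]], 0L)
  expect_identical(as.numeric(d), as.numeric(Xn[1, ]))
  # transmitted public values
  expect_equal(Xhat1$public$n, n)
  expect_equal(Xhat1$public$s_x, ctx$params$s_x)
})

test_that("weight encoding produces the |Y| x ceiling(f/n) plaintext grid", {
  ctx <- shared_he_ctx()
  f <- 2 * ctx$params$n + 10
  W_q <- matrix(sample(-100:100, f * 3, replace = TRUE), f, 3)
  enc <- he_encode_weights(W_q, c(7, 0, -7), ctx)
  expect_equal(enc$chunks, 3L)
  expect_length(enc$pt, 3)          # |Y| rows
  expect_length(enc$pt[[1]], 3)     # chunks per row
  # bias plaintext fills all slots with the bias value
  expect_true(all(enc$bias_allslots[[1]][[1]] == 7 %% ctx$params$t0))
  expect_true(all(enc$bias_allslots[[3]][[2]] ==
                  (-7) %% ctx$params$t1 + 0))
  expect_error(he_encode_weights(W_q, c(1, 2), ctx), "bias length")
})

test_that("the encrypted circuit equals the plaintext simulator slot for slot", {
  ctx <- shared_he_ctx()
  p <- ctx$params
  inst <- generate_random_inference_instance(2, 600, 3, seed = 19)
  Xq <- quantize_inputs(inst$X, p)
  Wq <- quantize_weights(inst$W, p)
  bq <- quantize_bias(inst$b, p)
  sim <- simulate_packed_matmul(Xq, Wq, bq, p)
  Xhat <- he_encrypt_inputs(Xq, ctx)
  enc <- he_encode_weights(Wq, bq, ctx)
  Yhat <- he_matmul(Xhat, enc, ctx)
  expect_equal(Yhat$rotations_per_dot, 13L)          # log2(8192)
  expect_equal(Yhat$total_rotations, 2 * 3 * 13 * 2) # pairs x ladder x moduli
  Yhat <- he_add_bias(Yhat, enc, ctx)
  expect_error(he_add_bias(Yhat, enc, ctx), "already added")
  res <- he_decrypt_decode(Yhat, ctx)
  expect_identical(res$slots$t0, sim$slots$t0)
  expect_identical(res$slots$t1, sim$slots$t1)
  expect_identical(res$Z_q, sim$Z_q)
  expect_gt(res$noise_budget, 0)
  # running the same circuit again gives identical decrypted values
  res2 <- he_decrypt_decode(he_add_bias(he_matmul(Xhat, enc, ctx), enc, ctx), ctx)
  expect_identical(res2$Z_q, res$Z_q)
})

test_that("zero weights leave exactly the biases; zero plaintexts stay zero", {
  ctx <- shared_he_ctx()
  p <- ctx$params
  inst <- generate_random_inference_instance(2, 50, 2, seed = 23,
                                             zero_weights = TRUE)
  Xq <- quantize_inputs(inst$X, p)
  bq <- quantize_bias(inst$b, p)
  Xhat <- he_encrypt_inputs(Xq, ctx)
  enc <- he_encode_weights(matrix(0, 50, 2), bq, ctx)
  res0 <- he_decrypt_decode(he_matmul(Xhat, enc, ctx), ctx)
  expect_true(all(res0$Z_q == 0))                    # all-zero slots pre-bias
  res <- he_decrypt_decode(he_add_bias(he_matmul(Xhat, enc, ctx), enc, ctx), ctx)
  expect_equal(res$Z_q, matrix(bq, 2, 2, byrow = TRUE))
})

test_that("noise budget survives the full-scale 40,960-feature dot product", {
  ctx <- shared_he_ctx()
  p <- ctx$params
  inst <- generate_random_inference_instance(1, 40960, 1, seed = 29)
  Xq <- quantize_inputs(inst$X, p)
  Wq <- quantize_weights(inst$W, p)
  bq <- quantize_bias(inst$b, p)
  Xhat <- he_encrypt_inputs(Xq, ctx)
  enc <- he_encode_weights(Wq, bq, ctx)
  res <- he_decrypt_decode(he_add_bias(he_matmul(Xhat, enc, ctx), enc, ctx), ctx)
  expect_gt(res$noise_budget, 0)
  expect_identical(res$Z_q, Xq %*% Wq + matrix(bq, 1, 1))
})

test_that("evaluation contexts built from public material compute but cannot decrypt", {
  ctx <- shared_he_ctx()
  p <- ctx$params
  blob <- he_public_blob(ctx)
  server <- he_evaluation_context(blob, p)
  expect_true(server$public_only)
  inst <- generate_random_inference_instance(1, 100, 2, seed = 31)
  Xq <- quantize_inputs(inst$X, p)
  Wq <- quantize_weights(inst$W, p)
  bq <- quantize_bias(inst$b, p)
  Xhat <- he_encrypt_inputs(Xq, ctx)                  # client encrypts
  enc <- he_encode_weights(Wq, bq, server)            # server encodes
  Yhat <- he_add_bias(he_matmul(Xhat, enc, server), enc, server)
  expect_error(he_decrypt_decode(Yhat, server), "no secret key")
  res <- he_decrypt_decode(Yhat, ctx)                 # client decrypts
  expect_identical(res$Z_q, Xq %*% Wq + matrix(bq, 1, 2, byrow = TRUE))
})

test_that("query and response envelopes round trip through files", {
  ctx <- shared_he_ctx()
  p <- ctx$params
  inst <- generate_random_inference_instance(2, 64, 2, seed = 37)
  Xq <- quantize_inputs(inst$X, p)
  Xhat <- he_encrypt_inputs(Xq, ctx)
  qf <- tempfile(fileext = ".bin")
  write_query(Xhat, qf)
  back <- read_query(qf)
  expect_identical(back$ct, Xhat$ct)
  expect_equal(back$f, 64)
  enc <- he_encode_weights(quantize_weights(inst$W, p),
                           quantize_bias(inst$b, p), ctx)
  Yhat <- he_add_bias(he_matmul(back, enc, ctx), enc, ctx)
  rf <- tempfile(fileext = ".bin")
  write_response(Yhat, rf, s_w = p$s_w)
  rback <- read_response(rf)
  expect_identical(rback$ct, Yhat$ct)
  expect_equal(rback$s_w, p$s_w)
  res <- he_decrypt_decode(rback, ctx)
  expect_identical(res$Z_q, Xq %*% quantize_weights(inst$W, p) +
                     matrix(quantize_bias(inst$b, p), 2, 2, byrow = TRUE))
})

test_that("the benchmark harness reports one row per method and batch size", {
  ctx <- shared_he_ctx()
  tab <- he_benchmark(ctx, batch_sizes = c(1L), f = 32L, n_outputs = 2L,
                      naive = TRUE, seed = 3)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$method, c("packed", "naive"))
  expect_true(all(tab$compute_s >= 0))
})
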