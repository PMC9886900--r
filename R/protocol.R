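#' Client/server file protocol for encrypted inference
#'
#' The trust boundary of the protocol is a pair of files: the client sends
#' one encrypted query (inputs only, under its public key) and receives one
#' encrypted response; the server never holds the secret key.  Envelopes
#' are length-prefixed binary: a single JSON header line carrying the public
#' values (`n`, the plaintext moduli, `s_x`, shapes), followed by each
#' ciphertext as an 8-byte little-endian length and its bytes.
#'
#' @name helr-protocol
#' @keywords internal
NULL

write_envelope <- function(header, raws, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hj <- charToRaw(as.character(jsonlite::toJSON(header, auto_unbox = TRUE)))
  writeBin(length(hj), con, size = 8, endian = "little")
  writeBin(hj, con)
  writeBin(length(raws), con, size = 8, endian = "little")
  for (r in raws) {
    writeBin(length(r), con, size = 8, endian = "little")
    writeBin(r, con)
  }
  invisible(path)
}

read_envelope <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, "integer", size = 8, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  nr <- readBin(con, "integer", size = 8, endian = "little")
  raws <- vector("list", nr)
  for (i in seq_len(nr)) {
    len <- readBin(con, "integer", size = 8, endian = "little")
    raws[[i]] <- readBin(con, "raw", len)
  }
  list(header = header, raws = raws)
}

#' Serialize an encrypted query or response
#'
#' @param x a `"packed_cipher_matrix"` (query) or `"encrypted_result"`
#'   (response).
#' @param path destination file.
#' @return The path, invisibly.
#' @export
write_query <- function(x, path) {
  stopifnot(inherits(x, "packed_cipher_matrix"))
  raws <- list()
  for (i in seq_len(x$n_rows))
    for (cc in seq_len(x$chunks))
      for (ti in 1:2) raws[[length(raws) + 1]] <- x$ct[[i]][[cc]][[ti]]
  header <- c(list(type = "query", n_rows = x$n_rows, f = x$f,
                   chunks = x$chunks), x$public)
  write_envelope(header, raws, path)
}

#' @rdname write_query
#' @export
read_query <- function(path) {
  env <- read_envelope(path)
  h <- env$header
  if (!identical(h$type, "query")) stop("not an encrypted query file")
  ct <- vector("list", h$n_rows)
  pos <- 1
  for (i in seq_len(h$n_rows)) {
    ct[[i]] <- vector("list", h$chunks)
    for (cc in seq_len(h$chunks)) {
      ct[[i]][[cc]] <- list(env$raws[[pos]], env$raws[[pos + 1]])
      pos <- pos + 2
    }
  }
  structure(list(ct = ct, n_rows = h$n_rows, f = h$f, chunks = h$chunks,
                 public = list(n = h$n, t0 = h$t0, t1 = h$t1, s_x = h$s_x)),
            class = "packed_cipher_matrix")
}

#' @rdname write_query
#' @param s_w weight scale exponent returned to the client with the
#'   response, per the protocol.
#' @export
write_response <- function(x, path, s_w) {
  stopifnot(inherits(x, "encrypted_result"))
  raws <- list()
  for (ct_i in seq_len(x$n_output_ct))
    for (ti in 1:2) raws[[length(raws) + 1]] <- x$ct[[ct_i]][[ti]]
  header <- list(type = "response", n_rows = x$n_rows,
                 n_outputs = x$n_outputs, n_output_ct = x$n_output_ct,
                 bias_added = x$bias_added, s_w = s_w)
  write_envelope(header, raws, path)
}

#' @rdname write_query
#' @export
read_response <- function(path) {
  env <- read_envelope(path)
  h <- env$header
  if (!identical(h$type, "response")) stop("not an encrypted response file")
  ct <- vector("list", h$n_output_ct)
  pos <- 1
  for (ct_i in seq_len(h$n_output_ct)) {
    ct[[ct_i]] <- list(env$raws[[pos]], env$raws[[pos + 1]])
    pos <- pos + 2
  }
  structure(list(ct = ct, n_rows = h$n_rows, n_outputs = h$n_outputs,
                 n_output_ct = h$n_output_ct, bias_added = h$bias_added,
                 s_w = h$s_w),
            class = "encrypted_result")
}

#' Prepare a trained model for the fixed-point protocol
#'
#' Normalizes the weights into `(-1, 1)` (argmax-invariant common rescale)
#' and quantizes weights and biases.  Returns the transposed `f x K` integer
#' weight matrix the server-side encoder expects.
#'
#' @param model a `"helr_model"`.
#' @param params an [fp_params()] object.
#' @return List with `W_q` (`f x K`), `b_q`, and the normalized `model`.
#' @export
prepare_model_for_encryption <- function(model, params) {
  nm <- normalize_model_weights(model)
  list(W_q = quantize_weights(t(nm$weights), params),
       b_q = quantize_bias(nm$bias, params),
       model = nm)
}
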