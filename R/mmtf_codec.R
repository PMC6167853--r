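#' MMTF binary field codecs
#'
#' Every binary array field of an MMTF document starts with a 12-byte
#' big-endian header — codec id (int32), element count (int32), codec
#' parameter (int32) — followed by the encoded payload.  The strategies
#' implemented here are the ones the format uses for coordinate and
#' annotation fields:
#'
#' | id | strategy |
#' |----|----------|
#' | 1  | 32-bit float pass-through |
#' | 2  | 8-bit signed integer pass-through |
#' | 3  | 16-bit signed integer pass-through |
#' | 4  | 32-bit signed integer pass-through |
#' | 5  | fixed-length UTF8 string array (param = bytes per string) |
#' | 6  | run-length encoded character array |
#' | 7  | run-length encoded 32-bit integer array |
#' | 8  | delta + run-length encoded 32-bit integer array |
#' | 9  | run-length encoded, integer-quantized float array (param = divisor) |
#' | 10 | delta + recursive-index (16-bit) quantized float array (param = divisor) |
#'
#' `mmtf_decode_field(mmtf_encode_field(x, codec, param))` is the identity
#' for integer, character and string data and exact to the 1/divisor
#' resolution for quantized floats.
#'
#' @param values the data to encode (numeric, integer or character vector
#'   as the codec requires).
#' @param codec integer codec id (1-10).
#' @param param codec parameter: string width for codec 5, divisor for
#'   codecs 9 and 10, otherwise 0.
#' @return `mmtf_encode_field()`: a raw vector (header + payload);
#'   `mmtf_decode_field()`: the decoded numeric/character vector.
#' @export
mmtf_encode_field <- function(values, codec, param = 0L) {
  payload <- switch(as.character(codec),
    "1" = writeBin(as.double(values), raw(), size = 4L, endian = "big"),
    "2" = int_bytes(values, 1L),
    "3" = int_bytes(values, 2L),
    "4" = int_bytes(values, 4L),
    "5" = {
      if (param < 1L) stop("codec 5 needs a positive string width")
      pad_strings(values, param)
    },
    "6" = int_bytes(rle_pairs(chars_to_codes(values)), 4L),
    "7" = int_bytes(rle_pairs(check_int(values)), 4L),
    "8" = int_bytes(rle_pairs(deltas(check_int(values))), 4L),
    "9" = int_bytes(rle_pairs(quantize(values, param)), 4L),
    "10" = int_bytes(recursive_index(deltas(quantize(values, param))), 2L),
    stop("unknown MMTF codec id: ", codec)
  )
  c(be_bytes(codec, 4L), be_bytes(length(values), 4L),
    be_bytes(param_bits(codec, param), 4L), payload)
}

#' @rdname mmtf_encode_field
#' @param bytes raw vector: 12-byte header plus payload.
#' @export
mmtf_decode_field <- function(bytes) {
  if (length(bytes) < 12L) stop("MMTF field shorter than its 12-byte header")
  codec <- be_value(bytes[1:4])
  count <- be_value(bytes[5:8])
  param <- be_value(bytes[9:12])
  payload <- bytes[-(1:12)]
  out <- switch(as.character(codec),
    "1" = readBin(payload, "double", n = length(payload) / 4L, size = 4L,
                  endian = "big"),
    "2" = bytes_int(payload, 1L),
    "3" = bytes_int(payload, 2L),
    "4" = bytes_int(payload, 4L),
    "5" = unpad_strings(payload, param),
    "6" = codes_to_chars(rle_expand(bytes_int(payload, 4L))),
    "7" = rle_expand(bytes_int(payload, 4L)),
    "8" = cumsum(rle_expand(bytes_int(payload, 4L))),
    "9" = rle_expand(bytes_int(payload, 4L)) / divisor_of(param),
    "10" = cumsum(recursive_unindex(bytes_int(payload, 2L))) /
      divisor_of(param),
    stop("unknown MMTF codec id: ", codec)
  )
  if (length(out) != count)
    stop("MMTF field: header count ", count, " does not match decoded ",
         "length ", length(out), " (codec ", codec, ")")
  out
}

# divisor params are written as int32 in practice (1000, 100); accept that.
param_bits <- function(codec, param) param
divisor_of <- function(param) if (param == 0) 1 else param

check_int <- function(v) {
  if (any(v != round(v))) stop("codec expects integer values")
  v
}

deltas <- function(v) {
  if (length(v) == 0L) return(numeric(0))
  c(v[1], diff(v))
}

quantize <- function(v, divisor) {
  if (divisor <= 0) stop("quantizing codec needs a positive divisor")
  round(v * divisor)
}

# run-length pairs (value, count)
rle_pairs <- function(v) {
  if (length(v) == 0L) return(numeric(0))
  r <- rle(as.numeric(v))
  as.numeric(rbind(r$values, r$lengths))
}

rle_expand <- function(pairs) {
  if (length(pairs) %% 2L != 0L)
    stop("run-length payload must hold (value, count) pairs")
  if (length(pairs) == 0L) return(numeric(0))
  vals <- pairs[seq(1L, length(pairs), by = 2L)]
  cnts <- pairs[seq(2L, length(pairs), by = 2L)]
  if (any(cnts < 0)) stop("negative run length")
  rep(vals, cnts)
}

# recursive indexing: values outside the 16-bit range are split into
# chunks of +/-32767 / -32768; the extreme values act as continuation
# markers
recursive_index <- function(v) {
  out <- numeric(0)
  for (x in v) {
    while (x >= 32767) { out <- c(out, 32767); x <- x - 32767 }
    while (x <= -32768) { out <- c(out, -32768); x <- x + 32768 }
    out <- c(out, x)
  }
  out
}

recursive_unindex <- function(stream) {
  out <- numeric(0)
  acc <- 0
  for (x in stream) {
    acc <- acc + x
    if (x != 32767 && x != -32768) {
      out <- c(out, acc)
      acc <- 0
    }
  }
  if (acc != 0) stop("recursive-index stream ends inside a value")
  out
}

chars_to_codes <- function(chars) {
  vapply(chars, function(s) {
    if (!nzchar(s)) 0L else utf8ToInt(s)
  }, integer(1), USE.NAMES = FALSE)
}

codes_to_chars <- function(codes) {
  vapply(codes, function(cd) {
    if (cd == 0) "" else intToUtf8(cd)
  }, character(1))
}

pad_strings <- function(strs, width) {
  out <- raw(0)
  for (s in strs) {
    b <- charToRaw(enc2utf8(s))
    if (length(b) > width)
      stop("string '", s, "' exceeds the fixed width ", width)
    out <- c(out, b, raw(width - length(b)))
  }
  out
}

unpad_strings <- function(payload, width) {
  if (width < 1L) stop("codec 5 needs a positive string width")
  if (length(payload) %% width != 0L)
    stop("string payload length not divisible by string width")
  n <- length(payload) %/% width
  vapply(seq_len(n), function(k) {
    b <- payload[((k - 1L) * width + 1L):(k * width)]
    b <- b[b != as.raw(0)]
    rawToChar(b)
  }, character(1))
}

# signed big-endian integers of 1/2/4-byte width <-> numeric vectors
int_bytes <- function(v, size) {
  rng <- 2^(8 * size)
  if (any(v < -rng / 2 | v >= rng / 2))
    stop("value out of range for ", size, "-byte integer")
  u <- ifelse(v < 0, v + rng, v)
  out <- raw(length(v) * size)
  for (k in seq_along(u)) out[((k - 1L) * size + 1L):(k * size)] <-
      be_bytes(u[k], size)
  out
}

bytes_int <- function(payload, size) {
  if (length(payload) %% size != 0L)
    stop("payload length not divisible by element size ", size)
  n <- length(payload) %/% size
  rng <- 2^(8 * size)
  vapply(seq_len(n), function(k) {
    v <- be_value(payload[((k - 1L) * size + 1L):(k * size)])
    if (v >= rng / 2) v - rng else v
  }, numeric(1))
}
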