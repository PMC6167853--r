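#' Minimal MessagePack encoder/decoder
#'
#' Implements the subset of the MessagePack serialization format needed to
#' carry MMTF documents: nil, booleans, integers (all int/uint widths),
#' 32/64-bit floats, strings, binary blobs, arrays and maps.  R mapping:
#' named lists are maps, unnamed lists and `msgpack_array` objects are
#' arrays, raw vectors are bin, length-1 character/numeric/logical values
#' are scalars.  Multi-byte values are big-endian per the format.
#'
#' @param x object to pack.
#' @return `msgpack_pack()`: a raw vector; `msgpack_unpack()`: an R object
#'   (maps become named lists, arrays lists, bin raw vectors).
#' @export
msgpack_pack <- function(x) {
  parts <- list()
  emit <- function(r) parts[[length(parts) + 1L]] <<- r
  pack_one(x, emit)
  do.call(c, parts)
}

#' Force array encoding for a vector
#' @param x atomic vector or list.
#' @export
as_msgpack_array <- function(x) {
  structure(as.list(x), class = "msgpack_array")
}

pack_one <- function(x, emit) {
  if (is.null(x)) return(emit(as.raw(0xc0)))
  if (inherits(x, "msgpack_array")) return(pack_array(unclass(x), emit))
  if (is.raw(x)) return(pack_bin(x, emit))
  if (is.list(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x))))
      return(pack_map(x, emit))
    return(pack_array(x, emit))
  }
  if (length(x) != 1L) return(pack_array(as.list(x), emit))
  if (is.logical(x)) return(emit(as.raw(if (x) 0xc3 else 0xc2)))
  if (is.character(x)) return(pack_str(x, emit))
  if (is.numeric(x)) {
    if (is.double(x) && x != round(x) || abs(x) >= 2^53)
      return(emit(c(as.raw(0xcb), writeBin(as.double(x), raw(),
                                           endian = "big"))))
    return(pack_int(x, emit))
  }
  stop("cannot pack object of class ", paste(class(x), collapse = "/"))
}

pack_int <- function(v, emit) {
  v <- as.numeric(v)
  if (v >= 0) {
    if (v < 128) emit(as.raw(v))
    else if (v < 256) emit(c(as.raw(0xcc), as.raw(v)))
    else if (v < 65536) emit(c(as.raw(0xcd), be_bytes(v, 2L)))
    else if (v < 2^32) emit(c(as.raw(0xce), be_bytes(v, 4L)))
    else emit(c(as.raw(0xcf), be_bytes(v, 8L)))
  } else {
    if (v >= -32) emit(as.raw(256 + v))
    else if (v >= -128) emit(c(as.raw(0xd0), as.raw(256 + v)))
    else if (v >= -32768) emit(c(as.raw(0xd1), be_bytes(v + 65536, 2L)))
    else if (v >= -2^31) emit(c(as.raw(0xd2), be_bytes(v + 2^32, 4L)))
    else stop("integer too small to pack: ", v)
  }
}

pack_str <- function(s, emit) {
  b <- charToRaw(enc2utf8(s))
  n <- length(b)
  if (n < 32) emit(c(as.raw(0xa0 + n), b))
  else if (n < 256) emit(c(as.raw(0xd9), as.raw(n), b))
  else if (n < 65536) emit(c(as.raw(0xda), be_bytes(n, 2L), b))
  else emit(c(as.raw(0xdb), be_bytes(n, 4L), b))
}

pack_bin <- function(b, emit) {
  n <- length(b)
  if (n < 256) emit(c(as.raw(0xc4), as.raw(n), b))
  else if (n < 65536) emit(c(as.raw(0xc5), be_bytes(n, 2L), b))
  else emit(c(as.raw(0xc6), be_bytes(n, 4L), b))
}

pack_array <- function(x, emit) {
  n <- length(x)
  if (n < 16) emit(as.raw(0x90 + n))
  else if (n < 65536) emit(c(as.raw(0xdc), be_bytes(n, 2L)))
  else emit(c(as.raw(0xdd), be_bytes(n, 4L)))
  for (el in x) pack_one(el, emit)
}

pack_map <- function(x, emit) {
  n <- length(x)
  if (n < 16) emit(as.raw(0x80 + n))
  else if (n < 65536) emit(c(as.raw(0xde), be_bytes(n, 2L)))
  else emit(c(as.raw(0xdf), be_bytes(n, 4L)))
  for (k in seq_len(n)) {
    pack_str(names(x)[k], emit)
    pack_one(x[[k]], emit)
  }
}

# big-endian unsigned bytes of a non-negative number (double arithmetic,
# exact below 2^53)
be_bytes <- function(v, nbytes) {
  out <- raw(nbytes)
  for (k in nbytes:1) {
    out[k] <- as.raw(v %% 256)
    v <- v %/% 256
  }
  out
}

be_value <- function(bytes) {
  v <- 0
  for (b in as.integer(bytes)) v <- v * 256 + b
  v
}

#' @rdname msgpack_pack
#' @param bytes raw vector holding one MessagePack object.
#' @export
msgpack_unpack <- function(bytes) {
  env <- new.env(parent = emptyenv())
  env$pos <- 1L
  env$bytes <- bytes
  out <- unpack_one(env)
  if (env$pos != length(bytes) + 1L)
    stop("trailing bytes after MessagePack object")
  out
}

take <- function(env, n) {
  if (n == 0) return(raw(0))
  if (env$pos + n - 1L > length(env$bytes))
    stop("truncated MessagePack data")
  out <- env$bytes[env$pos:(env$pos + n - 1L)]
  env$pos <- env$pos + n
  out
}

unpack_one <- function(env) {
  tag <- as.integer(take(env, 1L))
  if (tag < 0x80) return(tag)                       # positive fixint
  if (tag >= 0xe0) return(tag - 256L)               # negative fixint
  if (tag >= 0x80 && tag < 0x90) return(unpack_map(env, tag - 0x80))
  if (tag >= 0x90 && tag < 0xa0) return(unpack_array(env, tag - 0x90))
  if (tag >= 0xa0 && tag < 0xc0) return(unpack_str(env, tag - 0xa0))
  switch(as.character(tag),
    "192" = NULL,                                   # nil
    "194" = FALSE, "195" = TRUE,
    "196" = take(env, be_value(take(env, 1L))),     # bin8
    "197" = take(env, be_value(take(env, 2L))),     # bin16
    "198" = take(env, be_value(take(env, 4L))),     # bin32
    "202" = readBin(take(env, 4L), "double", size = 4L, endian = "big"),
    "203" = readBin(take(env, 8L), "double", size = 8L, endian = "big"),
    "204" = be_value(take(env, 1L)),                # uint8
    "205" = be_value(take(env, 2L)),
    "206" = be_value(take(env, 4L)),
    "207" = be_value(take(env, 8L)),                # uint64 (< 2^53 exact)
    "208" = signed_of(be_value(take(env, 1L)), 2^8),
    "209" = signed_of(be_value(take(env, 2L)), 2^16),
    "210" = signed_of(be_value(take(env, 4L)), 2^32),
    "211" = signed_of(be_value(take(env, 8L)), 2^64),
    "217" = unpack_str(env, be_value(take(env, 1L))),
    "218" = unpack_str(env, be_value(take(env, 2L))),
    "219" = unpack_str(env, be_value(take(env, 4L))),
    "220" = unpack_array(env, be_value(take(env, 2L))),
    "221" = unpack_array(env, be_value(take(env, 4L))),
    "222" = unpack_map(env, be_value(take(env, 2L))),
    "223" = unpack_map(env, be_value(take(env, 4L))),
    stop(sprintf("unsupported MessagePack tag 0x%02x", tag))
  )
}

signed_of <- function(v, range) if (v >= range / 2) v - range else v

unpack_str <- function(env, n) rawToChar(take(env, n))

unpack_array <- function(env, n) {
  out <- vector("list", n)
  for (k in seq_len(n)) {
    v <- unpack_one(env)
    if (!is.null(v)) out[[k]] <- v
  }
  out
}

unpack_map <- function(env, n) {
  out <- vector("list", n)
  keys <- character(n)
  for (k in seq_len(n)) {
    key <- unpack_one(env)
    keys[k] <- if (is.character(key)) key else as.character(key)
    v <- unpack_one(env)
    if (!is.null(v)) out[[k]] <- v
  }
  names(out) <- keys
  out
}
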