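#' GenBank feature-table parsing
#'
#' Parses the FEATURES block of a GenBank flat file into feature objects.
#' A feature has a key (e.g. `CDS`, `regulatory`), one or more locations on
#' the reference sequence and qualifiers.  The location grammar supports
#' `n`, `n..m`, `n^m`, `<n..m`, `n..>m`, `complement(...)`, `join(...)` and
#' `order(...)` with nesting; `complement(join(...))` and
#' `join(complement(...))` are both normalized to per-location strand
#' flags with the written order preserved.  Coordinates stay 1-based
#' inclusive as in the source format (see [location_to_zero_based()]).
#'
#' @param text GenBank text: a string, vector of lines, or a file path.
#' @return a list of features; each feature is a list with `key`,
#'   `locations` (data.frame: `first`, `last`, `strand`, `partial_start`,
#'   `partial_end`) and `qualifiers` (named list, `NA` for value-less
#'   qualifiers like `/pseudo`; names keep their written order).
#' @export
parse_genbank_features <- function(text) {
  lines <- as_lines(text)
  start <- grep("^FEATURES", lines)
  if (length(start) == 0L) {
    # accept a bare feature block (indented feature lines only)
    start <- 0L
  } else {
    start <- start[1L]
  }
  end <- length(lines)
  stop_markers <- grep("^(ORIGIN|CONTIG|BASE COUNT|//)", lines)
  stop_markers <- stop_markers[stop_markers > start]
  if (length(stop_markers)) end <- min(stop_markers) - 1L
  block <- lines[seq.int(start + 1L, length.out = max(0L, end - start))]

  # INSDC layout: feature keys start at column 6, continuations/qualifiers
  # at column 21
  is_key <- grepl("^ {1,10}\\S", block) & !grepl("^ {11}", block)
  features <- list()
  current <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    build_feature(cur$key, cur$body, cur$line)
  }
  for (i in seq_along(block)) {
    ln <- block[i]
    if (!nzchar(trimws(ln))) next
    if (is_key[i]) {
      f <- flush(current)
      if (!is.null(f)) features[[length(features) + 1L]] <- f
      parts <- regmatches(ln, regexec("^\\s*(\\S+)\\s*(.*)$", ln))[[1]]
      current <- list(key = parts[2], body = parts[3], line = i)
    } else {
      if (is.null(current))
        stop("GenBank: continuation line before any feature key (line ",
             i, ")")
      current$body <- c(current$body, trimws(ln))
    }
  }
  f <- flush(current)
  if (!is.null(f)) features[[length(features) + 1L]] <- f
  features
}

build_feature <- function(key, body, line) {
  # first the location (may span lines until the first '/name' qualifier)
  qual_start <- grep("^/", body)
  loc_lines <- if (length(qual_start)) body[seq_len(qual_start[1L] - 1L)]
               else body
  loc_text <- paste(loc_lines, collapse = "")
  locations <- tryCatch(parse_location(loc_text),
                        error = function(e)
                          stop("GenBank feature '", key, "' (line ", line,
                               "): ", conditionMessage(e)))
  quals <- parse_qualifiers(if (length(qual_start))
    body[seq.int(qual_start[1L], length(body))] else character(0))
  list(key = key, locations = locations, qualifiers = quals)
}

#' Parse a GenBank location string
#'
#' @param text e.g. `"complement(join(10..20,30..40))"`.
#' @return data.frame with columns `first`, `last`, `strand` (`"+"`/`"-"`),
#'   `partial_start`, `partial_end`; rows in written order.
#' @export
parse_location <- function(text) {
  text <- gsub("\\s", "", text)
  if (nchar(gsub("[^(]", "", text)) != nchar(gsub("[^)]", "", text)))
    stop("unbalanced parentheses in location '", text, "'")
  locs <- parse_location_node(text, minus = FALSE)
  do.call(rbind, locs)
}

parse_location_node <- function(text, minus) {
  if (grepl("^complement\\(", text)) {
    inner <- substr(text, nchar("complement(") + 1L, nchar(text) - 1L)
    return(parse_location_node(inner, !minus))
  }
  if (grepl("^(join|order)\\(", text)) {
    open <- regexpr("(", text, fixed = TRUE)
    inner <- substr(text, open + 1L, nchar(text) - 1L)
    parts <- split_top_level(inner)
    return(do.call(c, lapply(parts, parse_location_node, minus = minus)))
  }
  # simple span: n, n..m, n^m with optional < / > partial markers
  m <- regexec("^(<?)(\\d+)(?:(\\.\\.|\\^)(>?)(\\d+))?$", text,
               perl = TRUE)[[1]]
  g <- regmatches(text, list(m))[[1]]
  if (length(g) == 0L) stop("cannot parse location span '", text, "'")
  first <- as.integer(g[3])
  last <- if (nzchar(g[6])) as.integer(g[6]) else first
  if (first > last) stop("location first > last in '", text, "'")
  list(data.frame(
    first = first, last = last,
    strand = if (minus) "-" else "+",
    partial_start = g[2] == "<",
    partial_end = g[5] == ">",
    stringsAsFactors = FALSE
  ))
}

# split "a,b(c,d),e" on commas at parenthesis depth 0
split_top_level <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  cut <- which(chars == "," & depth == 0L)
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  mapply(function(s, e) paste(chars[s:e], collapse = ""), starts, ends)
}

# Qualifier lines: /name="value" (value may continue over lines),
# /name=value, bare /name.  Continued quoted values are joined with a
# single space, except translation-like ones which are joined seamlessly.
parse_qualifiers <- function(lines) {
  quals <- list()
  i <- 1L
  seamless <- c("translation")
  while (i <= length(lines)) {
    ln <- lines[i]
    m <- regmatches(ln, regexec("^/([^=/\\s]+)(?:=(.*))?$", ln,
                                perl = TRUE))[[1]]
    if (length(m) == 0L) stop("cannot parse qualifier line '", ln, "'")
    name <- m[2]
    value <- m[3]
    if (!nzchar(value) && !grepl("=", ln)) {
      quals[[length(quals) + 1L]] <- stats::setNames(list(NA), name)
      i <- i + 1L
      next
    }
    if (startsWith(value, "\"")) {
      parts <- sub("^\"", "", value)
      while (!grepl("\"$", parts[length(parts)]) && i < length(lines)) {
        i <- i + 1L
        parts <- c(parts, lines[i])
      }
      parts[length(parts)] <- sub("\"$", "", parts[length(parts)])
      sep <- if (name %in% seamless) "" else " "
      value <- paste(parts, collapse = sep)
    }
    quals[[length(quals) + 1L]] <- stats::setNames(list(value), name)
    i <- i + 1L
  }
  out <- unlist(quals, recursive = FALSE)
  if (is.null(out)) out <- stats::setNames(list(), character(0))
  out
}

#' Render features back to a GenBank-style feature block
#'
#' The inverse of [parse_genbank_features()] up to whitespace; parse,
#' render and re-parse is a fixed point.
#'
#' @param features list of features.
#' @return character vector of feature-block lines.
#' @export
render_genbank_features <- function(features) {
  out <- "FEATURES             Location/Qualifiers"
  for (f in features) {
    loc <- render_location(f$locations)
    out <- c(out, sprintf("     %-16s%s", f$key, loc))
    for (k in seq_along(f$qualifiers)) {
      name <- names(f$qualifiers)[k]
      v <- f$qualifiers[[k]]
      line <- if (length(v) == 1L && is.na(v)) paste0("/", name)
              else paste0("/", name, "=\"", v, "\"")
      out <- c(out, sprintf("%21s%s", "", line))
    }
  }
  out
}

render_location <- function(locs) {
  spans <- vapply(seq_len(nrow(locs)), function(i) {
    s <- paste0(if (locs$partial_start[i]) "<" else "", locs$first[i],
                if (locs$last[i] != locs$first[i] ||
                    locs$partial_end[i]) paste0("..",
                  if (locs$partial_end[i]) ">" else "", locs$last[i]) else "")
    if (locs$strand[i] == "-") paste0("complement(", s, ")") else s
  }, character(1))
  if (length(spans) > 1L) paste0("join(", paste(spans, collapse = ","), ")")
  else spans
}

#' Convert 1-based inclusive locations to 0-based half-open
#'
#' GenBank coordinates are kept 1-based inclusive at the format boundary;
#' this helper converts to the 0-based half-open convention used for
#' sequence indexing, so `span = end - start` equals the span length.
#'
#' @param locs location data.frame from [parse_location()].
#' @return data.frame with `start` (0-based) and `end` (exclusive) columns
#'   alongside the strand/partial flags.
#' @export
location_to_zero_based <- function(locs) {
  data.frame(start = locs$first - 1L, end = locs$last,
             strand = locs$strand,
             partial_start = locs$partial_start,
             partial_end = locs$partial_end,
             stringsAsFactors = FALSE)
}
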