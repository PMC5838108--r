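`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == as.integer(x)
}

stop_tract <- function(fmt, ..., call. = FALSE) {
  stop(sprintf(fmt, ...), call. = call.)
}

warn_tract <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

#' Shortest round-trip decimal formatting
#'
#' Formats doubles with the fewest significant digits that still read back to
#' the identical IEEE value, so text files carry full precision without noise
#' digits. `NA` becomes the empty string.
#'
#' @param x numeric vector
#' @return character vector, same length
#' @noRd
fmt_num <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- ""
  todo <- which(!is.na(x))
  if (!length(todo)) return(out)
  xi <- x[todo]
  res <- formatC(xi, digits = 15L, format = "g", width = 1L)
  for (d in c(16L, 17L)) {
    bad <- suppressWarnings(as.numeric(res)) != xi
    bad[is.na(bad)] <- TRUE
    if (!any(bad)) break
    res[bad] <- formatC(xi[bad], digits = d, format = "g", width = 1L)
  }
  out[todo] <- res
  out
}

# RFC 3986 percent-encoding over UTF-8 bytes; everything outside the
# unreserved set [A-Za-z0-9._~-] is escaped. Hand-rolled because the codec
# must round-trip multi-byte characters byte-exactly.
percent_encode <- function(s) {
  vapply(s, function(one) {
    if (is.na(one)) return(NA_character_)
    bytes <- charToRaw(enc2utf8(one))
    unreserved <- c(as.raw(0x30:0x39), as.raw(0x41:0x5A), as.raw(0x61:0x7A),
                    as.raw(c(0x2D, 0x2E, 0x5F, 0x7E)))
    ok <- bytes %in% unreserved
    chars <- character(length(bytes))
    chars[ok] <- vapply(bytes[ok], rawToChar, character(1))
    chars[!ok] <- sprintf("%%%02X", as.integer(bytes[!ok]))
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

percent_decode <- function(s) {
  hex <- c(as.raw(0x30:0x39), as.raw(0x41:0x46), as.raw(0x61:0x66))
  vapply(s, function(one) {
    if (is.na(one)) return(NA_character_)
    if (!grepl("%", one, fixed = TRUE)) {
      out <- one
    } else {
      inb <- charToRaw(one)
      outb <- raw(length(inb))
      i <- 1L; j <- 0L
      while (i <= length(inb)) {
        b <- inb[i]
        if (b == as.raw(0x25)) {
          if (i + 2L > length(inb) || !(inb[i + 1L] %in% hex) ||
              !(inb[i + 2L] %in% hex)) {
            stop_tract("malformed percent-escape in %s", sQuote(one))
          }
          b <- as.raw(strtoi(rawToChar(inb[(i + 1L):(i + 2L)]), 16L))
          i <- i + 3L
        } else {
          i <- i + 1L
        }
        j <- j + 1L
        outb[j] <- b
      }
      out <- rawToChar(outb[seq_len(j)])
    }
    Encoding(out) <- "UTF-8"
    out
  }, character(1), USE.NAMES = FALSE)
}

# Seeded evaluation that never disturbs the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}
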